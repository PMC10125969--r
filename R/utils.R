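# Shared internal helpers: covariate level sets, simplex draws, small checks.

# Canonical covariate level sets. First level of each is the reference
# (the "1.00 (reference)" rows of the multivariable OR table); the
# T-category reference is the lowest level present in the fitting data.
covariate_levels <- function() {
  list(
    age_group          = c("<60", "60-69", "70-79", ">=80"),
    sex                = c("male", "female"),
    grade              = c("G1", "G2", "G3"),
    t_category         = c("T2", "T3", "T4"),
    lymphatic_invasion = c("L0", "L1+"),
    venous_invasion    = c("V0", "V1+")
  )
}

covariate_names <- function() names(covariate_levels())

# Names of all non-reference indicator columns, in canonical order.
indicator_names <- function() {
  lv <- covariate_levels()
  unlist(lapply(names(lv), function(nm) paste(nm, lv[[nm]][-1], sep = "_")),
         use.names = FALSE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Dirichlet draws via normalized gammas; rows are simplex vectors.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Binary labels as a 0/1 integer vector, whatever the input encoding.
as_binary01 <- function(x, name = "labels") {
  if (length(x) == 0L) return(integer(0))
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (0/1) with no missing values.", name))
  }
  as.integer(x)
}

# Quantitation tables are wide tibbles: case_id then cl_1 .. cl_K.
quant_col <- function(ids) {
  if (length(ids) == 0L) return(character(0))
  paste0("cl_", ids)
}

quant_K <- function(quants) {
  sum(grepl("^cl_[0-9]+$", names(quants)))
}

# Extract the fraction matrix for the given cluster ids, rows aligned to
# the supplied case ids. Errors on any case without a quantitation row.
quant_matrix <- function(quants, case_ids, ml_ids) {
  idx <- match(case_ids, quants$case_id)
  if (anyNA(idx)) {
    abort(sprintf("missing quantitation vector for case(s): %s",
                  paste(head(case_ids[is.na(idx)], 5L), collapse = ", ")))
  }
  cols <- quant_col(ml_ids)
  missing_cols <- setdiff(cols, names(quants))
  if (length(missing_cols) > 0L) {
    abort(sprintf("quantitation table has no column(s) %s",
                  paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(quants[idx, cols, drop = FALSE])
  rownames(m) <- case_ids
  m
}

`%||%` <- rlang::`%||%`
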