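# Internal helpers shared across modules.

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# One Dirichlet draw per row of `alpha` (n x p matrix), via independent gammas.
rdirichlet_rows <- function(alpha) {
  g <- matrix(rgamma(length(alpha), shape = alpha, rate = 1),
              nrow = nrow(alpha), ncol = ncol(alpha))
  # a gamma draw can underflow to 0 at tiny shape; keep rows strictly positive
  g[g == 0] <- .Machine$double.xmin
  g / rowSums(g)
}

# Derive a reproducible sub-stream seed for a named operation from a base seed.
# Keeps results decoupled across operations while everything flows from one
# configured seed. Stays below 2^31 - 1.
derive_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L) + 1L
}

with_op_seed <- function(seed, op, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, op))
  force(code)
}

# Convert a samples-in-rows abundance tibble (first column sample_id) to a
# numeric matrix with sample_id rownames.
abundance_matrix <- function(table) {
  stopifnot(is.data.frame(table), "sample_id" %in% names(table))
  m <- as.matrix(table[setdiff(names(table), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(table$sample_id)
  m
}

matrix_to_table <- function(m) {
  out <- tibble::as_tibble(m)
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
}

feature_ids <- function(table) setdiff(names(table), "sample_id")

# Validate an abundance table against the compositional invariants.
# Rows must be non-negative and sum to 1 within `tol_error`; deviations within
# `tol_renorm` are renormalized with a message.
validate_abundance_table <- function(table, tol_renorm = 1e-3, tol_error = 1e-3,
                                     renormalize = TRUE) {
  if (!is.data.frame(table) || !"sample_id" %in% names(table)) {
    abort("abundance table must be a data frame with a `sample_id` column",
          class = "gutmaturity_validation_error")
  }
  if (anyDuplicated(table$sample_id)) {
    abort(paste0("duplicated sample ids: ",
                 paste(unique(table$sample_id[duplicated(table$sample_id)]),
                       collapse = ", ")),
          class = "gutmaturity_validation_error")
  }
  feats <- feature_ids(table)
  if (anyDuplicated(feats)) {
    abort("duplicated feature ids in abundance table",
          class = "gutmaturity_validation_error")
  }
  m <- abundance_matrix(table)
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("abundance values must be finite and non-negative",
          class = "gutmaturity_validation_error")
  }
  rs <- rowSums(m)
  off <- abs(rs - 1)
  if (any(off > tol_error)) {
    bad <- rownames(m)[off > tol_error]
    abort(paste0("abundance rows do not sum to 1 (tolerance ", tol_error,
                 "): ", paste(head(bad, 5), collapse = ", ")),
          class = "gutmaturity_validation_error")
  }
  if (renormalize && any(off > 1e-6)) {
    inform(paste0("renormalizing ", sum(off > 1e-6),
                  " abundance rows with sums within ", tol_renorm, " of 1"))
    m <- m / rs
    return(matrix_to_table(m))
  }
  table
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || x < min || x != round(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min),
          class = "gutmaturity_validation_error")
  }
  as.integer(x)
}
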