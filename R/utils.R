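# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Enumerate the unordered index pairs of a symmetric matrix fill
#'
#' Returns the (i, j) index pairs, i < j, visited when filling the upper
#' triangle of a symmetric similarity matrix over `n` labels. This is the
#' exact enumeration used by [term_matrix()] and [entity_matrix()], exposed
#' so that pair counts over large label sets can be audited without
#' materialising the matrix itself.
#'
#' @param n number of labels (non-negative integer).
#' @return A two-column integer matrix with `choose(n, 2)` rows.
#' @examples
#' upper_pairs(4) # 6 pairs
#' @export
upper_pairs <- function(n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 0L)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  cbind(i = i, j = j)
}

# Fixed-width score formatting used in every TSV export: reproducible diffs.
fmt_score <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6f", x))
}

# Condition constructors: usage errors (bad flags/names, exit 2) vs data
# errors (bad inputs discovered while computing, exit 1).
usage_error <- function(msg) {
  stop(structure(
    class = c("ontosim_usage_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

data_error <- function(msg) {
  stop(structure(
    class = c("ontosim_data_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}
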