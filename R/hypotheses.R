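# Hypothesis matrices for mate choice among the four cross-fostered
# lineage types DD, DW, WD, WW (first letter = genetic origin, second =
# rearing culture). Each hypothesis allows a subset of the 16 female-type x
# male-type cells:
#  H1  innate preference for a genetic trait: matching first letters.
#  H2  learnt preference for a genetic trait (mutual imprinting on the
#      parental morphotype): each partner's origin equals the other's
#      rearing letter.
#  H3  learnt preference for a cultural trait (song): matching second
#      letters.
#  H1W wild-origin birds prefer domesticated-origin partners: mixed-origin
#      cells.

LINEAGE_TYPES <- c("DD", "DW", "WD", "WW")

#' Allowed-cell indicator matrix of a mating hypothesis
#'
#' @param name `"H1"`, `"H2"`, `"H3"`, or `"H1W"`.
#' @return 4 x 4 logical matrix (rows = female type, cols = male type).
#' @export
hypothesis_spec <- function(name = c("H1", "H2", "H3", "H1W")) {
  name <- match.arg(name)
  f1 <- substr(LINEAGE_TYPES, 1, 1); f2 <- substr(LINEAGE_TYPES, 2, 2)
  allowed <- switch(name,
    H1 = outer(f1, f1, "=="),
    H2 = outer(seq_len(4), seq_len(4), function(i, j) f1[j] == f2[i] & f1[i] == f2[j]),
    H3 = outer(f2, f2, "=="),
    H1W = outer(f1, f1, "!="))
  dimnames(allowed) <- list(female = LINEAGE_TYPES, male = LINEAGE_TYPES)
  structure(list(name = name, allowed = allowed), class = "hypothesis_spec")
}

#' Expected 4 x 4 pair-type matrix under a hypothesis
#'
#' `total_pairs` is distributed over the allowed cells proportionally to the
#' product of available female and male counts per cell (so unbalanced
#' compositions are handled); disallowed cells get 0.
#'
#' @param hyp a [hypothesis_spec()] (or its name).
#' @param composition counts per type: `data.frame` with `type`,
#'   `n_female`, `n_male`, or a single named vector used for both sexes.
#' @param total_pairs total number of pairs to distribute.
#' @return 4 x 4 numeric matrix of class `pair_type_matrix`.
#' @export
expected_matrix <- function(hyp, composition, total_pairs) {
  if (is.character(hyp)) hyp <- hypothesis_spec(hyp)
  if (is.numeric(composition) && !is.null(names(composition))) {
    composition <- data.frame(type = names(composition),
                              n_female = as.numeric(composition),
                              n_male = as.numeric(composition))
  }
  nf <- setNames(rep(0, 4), LINEAGE_TYPES)
  nm <- nf
  nf[composition$type] <- composition$n_female
  nm[composition$type] <- composition$n_male
  w <- outer(nf, nm) * hyp$allowed
  ds_assert(sum(w) > 0, "no allowed cell has both females and males")
  M <- total_pairs * w / sum(w)
  dimnames(M) <- list(female = LINEAGE_TYPES, male = LINEAGE_TYPES)
  structure(M, class = c("pair_type_matrix", "matrix", "array"))
}

lineage_type <- function(code) {
  ds_assert(all(nchar(code) >= 2), paste("lineage code too short:",
            paste(unique(code[nchar(code) < 2]), collapse = ", ")))
  t <- substr(code, 1, 2)
  bad <- setdiff(unique(t), LINEAGE_TYPES)
  ds_assert(length(bad) == 0, paste("unknown lineage code(s):",
            paste(bad, collapse = ", ")))
  t
}

#' Observed 4 x 4 pair-type matrix
#'
#' @param pairs a `pair_bond_set` or `data.table` with `female_id`,
#'   `male_id`.
#' @param birds bird metadata providing `lineage_code`.
#' @return 4 x 4 count matrix of class `pair_type_matrix`.
#' @export
observed_matrix <- function(pairs, birds) {
  pt <- if (inherits(pairs, "pair_bond_set")) pairs$pairs else as.data.table(pairs)
  M <- matrix(0, 4, 4, dimnames = list(female = LINEAGE_TYPES,
                                       male = LINEAGE_TYPES))
  if (nrow(pt) > 0) {
    code <- setNames(birds$lineage_code, birds$bird_id)
    ft <- lineage_type(code[pt$female_id])
    mt <- lineage_type(code[pt$male_id])
    for (i in seq_along(ft)) M[ft[i], mt[i]] <- M[ft[i], mt[i]] + 1
  }
  structure(M, class = c("pair_type_matrix", "matrix", "array"))
}

#' Pearson correlation between two pair-type matrices
#'
#' Computed over the flattened 16 cells; the two-tailed p-value uses the
#' t-transform `t = r sqrt(n-2) / sqrt(1-r^2)` with `df = 14`.
#'
#' @param a,b 4 x 4 matrices.
#' @return list: `r`, `t`, `df`, `p`.
#' @export
matrix_correlation <- function(a, b) {
  av <- as.vector(a); bv <- as.vector(b)
  ds_assert(sd(av) > 0 && sd(bv) > 0,
            "constant matrix: correlation undefined")
  r <- cor(av, bv)
  n <- length(av)
  t <- r * sqrt(n - 2) / sqrt(max(1e-15, 1 - r^2))
  list(r = r, t = t, df = n - 2L, p = 2 * pt(-abs(t), n - 2))
}

#' Repeatability of pairing patterns between replicates
#'
#' Pearson r of the 16 cell counts across two replicate matrices; the cells
#' sharing a song dialect (matching rearing letters) are flagged for
#' reporting.
#'
#' @param matrix_rep1,matrix_rep2 4 x 4 matrices with identical indexing.
#' @return list: `r`, `p`, `df`, and `song_assortative_cells` (logical 4x4).
#' @export
replicate_repeatability <- function(matrix_rep1, matrix_rep2) {
  mc <- matrix_correlation(matrix_rep1, matrix_rep2)
  mc$song_assortative_cells <- hypothesis_spec("H3")$allowed
  mc
}

# simplex grid with given step; returns H x n_grid weight matrix
simplex_grid <- function(H, step) {
  k <- round(1 / step)
  if (H == 1) return(matrix(1, 1, 1))
  combos <- utils::combn(k + H - 1, H - 1)
  n <- ncol(combos)
  W <- matrix(0, H, n)
  for (i in seq_len(n)) {
    cuts <- c(0L, combos[, i], k + H)
    W[, i] <- (diff(cuts) - 1L) / k
  }
  W
}

#' Best-correlating mixture of hypothesis matrices
#'
#' Simplex grid search over nonnegative weights summing to 1, maximizing
#' the Pearson correlation of the weighted expected matrix with the
#' observed one. Ties are resolved toward sparser weight vectors.
#'
#' @param observed observed 4 x 4 matrix.
#' @param expected_list named list of >= 2 expected matrices (one per
#'   hypothesis), or a single-element list (returned with weight 1).
#' @param grid_step grid resolution in `(0, 0.5]`.
#' @return list of class `mixture_weights`: `weights` (named),
#'   `correlation`.
#' @export
fit_mixture <- function(observed, expected_list, grid_step = 0.01) {
  ds_assert(grid_step > 0 && grid_step <= 0.5, "grid_step must be in (0, 0.5]")
  H <- length(expected_list)
  E <- vapply(expected_list, as.vector, numeric(16))
  obs <- as.vector(observed)
  if (H == 1) {
    return(structure(list(weights = setNames(1, names(expected_list)),
                          correlation = matrix_correlation(observed, expected_list[[1]])$r),
                     class = "mixture_weights"))
  }
  W <- simplex_grid(H, grid_step)
  M <- E %*% W                       # 16 x n_grid candidate mixtures
  Mc <- M - rep(colMeans(M), each = 16)
  oc <- obs - mean(obs)
  denom <- sqrt(colSums(Mc^2)) * sqrt(sum(oc^2))
  r <- as.vector(crossprod(Mc, oc)) / pmax(denom, 1e-300)
  r[denom < 1e-12] <- -Inf           # constant mixtures cannot win
  best <- max(r)
  cand <- which(r >= best - 1e-12)
  if (length(cand) > 1) {
    nz <- colSums(W[, cand, drop = FALSE] > 0)
    cand <- cand[order(nz)][1]
  }
  structure(list(weights = setNames(W[, cand[1]], names(expected_list)),
                 correlation = r[cand[1]]),
            class = "mixture_weights")
}

#' @export
print.mixture_weights <- function(x, ...) {
  cat("mixture weights:", paste(sprintf("%s=%.2f", names(x$weights), x$weights),
                                collapse = " "),
      sprintf("(r = %.3f)\n", x$correlation))
  invisible(x)
}
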