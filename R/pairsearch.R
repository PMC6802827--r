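#' Between/within-class separation score
#'
#' `J = s_b / s_w` where `s_w = sum_k (1/N_k) sum_{n in k} ||x_n - m_k||^2`
#' (within-class spread) and `s_b = (1/K) sum_k ||m_k - m||^2` with `m` the
#' unweighted mean of the class means (between-class spread). Higher J means
#' stronger class discrimination of the feature subset.
#'
#' @param x Numeric samples-by-features matrix (a vector is treated as one
#'   feature).
#' @param y Class labels, one per row; every class must be non-empty.
#' @return Object of class `separation_score`: list with `j`, `s_w`, `s_b`
#'   and the class means.
#' @export
#' @examples
#' separation_score(c(0, 2, 4, 6), c("a", "a", "b", "b"))$j  # 2
separation_score <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  sc <- class_scatter(x, y)
  s_w <- sum(diag(sc$sw))
  s_b <- sum(diag(sc$sb))
  if (s_w == 0) {
    stop("degenerate within-class spread (s_w = 0): J is unbounded",
         call. = FALSE)
  }
  structure(list(j = s_b / s_w, s_w = s_w, s_b = s_b,
                 class_means = sc$class_means, classes = classes),
            class = "separation_score")
}

# Reproducible stimulus subsets: the resample sequence depends only on the
# unit set, fraction, count and seed, so a per-pair rescoring with the same
# seed sees exactly the subsets the exhaustive search used.
draw_stimulus_resamples <- function(units, fraction, n_resamples, seed) {
  m <- floor(fraction * length(units))
  if (m < 2) stop("resample fraction keeps fewer than two stimuli",
                  call. = FALSE)
  draw <- function() replicate(n_resamples, sample(units, m),
                               simplify = FALSE)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Per-feature within/between spreads for a 2-class split; the spreads of a
# feature subset are the sums of its per-feature terms, which is what makes
# the exhaustive pair scan cheap.
colwise_spreads <- function(x, idx1, idx2) {
  x1 <- x[idx1, , drop = FALSE]
  x2 <- x[idx2, , drop = FALSE]
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  sw <- colSums(sweep(x1, 2, m1)^2) / nrow(x1) +
    colSums(sweep(x2, 2, m2)^2) / nrow(x2)
  m <- (m1 + m2) / 2
  sb <- ((m1 - m)^2 + (m2 - m)^2) / 2
  list(sw = sw, sb = sb)
}

#' Resampling-stabilised separation score
#'
#' Subsamples the stimuli (paired across the two tissue states: a stimulus
#' is kept or dropped in both class blocks together) to
#' `floor(fraction * n_stimuli)` units, computes the separation score on
#' each subset, and summarises the `n_resamples` values -- by their maximum
#' by default. Degenerate subsets (`s_w = 0`) are skipped with a warning.
#'
#' @param x Samples-by-features matrix or vector.
#' @param y Two class labels, one per row.
#' @param stimulus Resampling unit per row (stimulus ids); when `NULL`,
#'   every row is its own unit (unpaired subsampling).
#' @param n_resamples Number of subsets (default 100).
#' @param fraction Fraction of units kept per subset (default 0.8; 1 makes
#'   every subset the full data, so the score equals the raw J).
#' @param seed Optional integer; fixes the subset sequence.
#' @param summary `"max"` (default), `"median"` or `"min"` over the
#'   resampled J values. The maximum follows the method as published;
#'   median/min are more conservative alternatives.
#' @return The summarised score, with the per-resample values as attribute
#'   `resamples`.
#' @export
resampled_score <- function(x, y, stimulus = NULL, n_resamples = 100,
                            fraction = 0.8, seed = NULL,
                            summary = c("max", "median", "min")) {
  summary <- match.arg(summary)
  x <- as.matrix(x)
  y <- as.character(y)
  stimulus <- stimulus %||% as.character(seq_len(nrow(x)))
  units <- unique(stimulus)
  subsets <- draw_stimulus_resamples(units, fraction, n_resamples, seed)
  js <- vapply(subsets, function(u) {
    keep <- stimulus %in% u
    sc <- tryCatch(separation_score(x[keep, , drop = FALSE], y[keep]),
                   error = function(e) NULL)
    if (is.null(sc)) NA_real_ else sc$j
  }, numeric(1))
  if (anyNA(js)) {
    if (all(is.na(js))) stop("every resample was degenerate", call. = FALSE)
    warning(sum(is.na(js)), " degenerate resample(s) skipped",
            call. = FALSE)
  }
  out <- switch(summary,
                max = max(js, na.rm = TRUE),
                median = stats::median(js, na.rm = TRUE),
                min = min(js, na.rm = TRUE))
  attr(out, "resamples") <- js
  out
}

#' Exhaustive search for the most discriminative protein pair
#'
#' Scores every unordered pair of proteins by the resampled separation score
#' of its two-column submatrix and ranks all `p(p-1)/2` pairs. All pairs are
#' scored on the same stimulus subsets (drawn once from `seed`), so scores
#' are directly comparable and identical to a per-pair [resampled_score()]
#' call with the same seed. The top pair's two-dimensional linear decision
#' boundary is fitted with [decision_boundary()].
#'
#' @param data Response tibble with both states stacked (protein columns
#'   plus `state` and `stimulus_id`), or a numeric matrix.
#' @param labels Class labels; default `data$state` for tibble input.
#' @param stimulus Resampling units; default `data$stimulus_id` for tibble
#'   input.
#' @param n_resamples,fraction,seed,summary Passed to the resampling scheme
#'   (defaults 100 subsets of 80% of the stimuli, summarised by the max).
#' @return Object of class `pair_search`: list with `ranking` (tibble:
#'   `protein_1`, `protein_2`, `pair`, `j_raw`, `j_resampled`, `rank`),
#'   `best_pair`, `boundary`, `best_data` (tibble of the top pair's columns
#'   with labels, for plotting) and the search parameters.
#' @export
exhaustive_pair_search <- function(data, labels = NULL, stimulus = NULL,
                                   n_resamples = 100, fraction = 0.8,
                                   seed = NULL,
                                   summary = c("max", "median", "min")) {
  summary <- match.arg(summary)
  if (is.data.frame(data)) {
    labels <- labels %||% data$state
    stimulus <- stimulus %||% data$stimulus_id
    x <- as_protein_matrix(data)
  } else {
    x <- as.matrix(data)
    storage.mode(x) <- "double"
  }
  if (is.null(labels)) stop("class labels required", call. = FALSE)
  y <- as.character(labels)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("need exactly two classes", call. = FALSE)
  p <- ncol(x)
  if (p < 3) stop("need at least three proteins", call. = FALSE)
  proteins <- colnames(x) %||% paste0("V", seq_len(p))
  stimulus <- stimulus %||% as.character(seq_len(nrow(x)))
  units <- unique(stimulus)
  subsets <- draw_stimulus_resamples(units, fraction, n_resamples, seed)
  i1 <- which(y == classes[1])
  i2 <- which(y == classes[2])
  ui <- rep(seq_len(p), times = p - seq_len(p))
  uj <- unlist(lapply(seq_len(p - 1), function(i) (i + 1):p))
  pair_j <- function(keep) {
    sp <- colwise_spreads(x[keep, , drop = FALSE],
                          which(y[keep] == classes[1]),
                          which(y[keep] == classes[2]))
    sw <- sp$sw[ui] + sp$sw[uj]
    sb <- sp$sb[ui] + sp$sb[uj]
    ifelse(sw == 0, NA_real_, sb / sw)
  }
  res_j <- vapply(subsets, function(u) pair_j(stimulus %in% u),
                  numeric(length(ui)))
  res_j <- matrix(res_j, nrow = length(ui))
  j_resampled <- apply(res_j, 1, function(v) {
    if (all(is.na(v))) NA_real_ else switch(
      summary,
      max = max(v, na.rm = TRUE),
      median = stats::median(v, na.rm = TRUE),
      min = min(v, na.rm = TRUE))
  })
  j_raw <- pair_j(rep(TRUE, nrow(x)))
  ranking <- tibble::tibble(
    protein_1 = proteins[ui], protein_2 = proteins[uj],
    pair = paste(proteins[ui], proteins[uj], sep = ":"),
    j_raw = unname(j_raw), j_resampled = unname(j_resampled))
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$j_resampled),
                            .data$pair)
  ranking$rank <- seq_len(nrow(ranking))
  best <- c(ranking$protein_1[1], ranking$protein_2[1])
  x2 <- x[, best, drop = FALSE]
  boundary <- decision_boundary(x2, y)
  best_data <- tibble::tibble(state = y, stimulus_id = stimulus)
  best_data[best] <- as.data.frame(x2)
  structure(list(ranking = ranking, best_pair = best, boundary = boundary,
                 best_data = best_data,
                 params = list(n_resamples = n_resamples,
                               fraction = fraction, seed = seed,
                               summary = summary)),
            class = "pair_search")
}

#' @export
print.pair_search <- function(x, ...) {
  cat("Exhaustive pair search over", nrow(x$ranking), "protein pairs\n")
  cat("best pair:", paste(x$best_pair, collapse = " / "),
      " (resampled J =", signif(x$ranking$j_resampled[1], 4), ")\n")
  print(head(x$ranking, 5))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pair_search <- function(x, ...) x$ranking

#' @exportS3Method generics::glance
glance.pair_search <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$ranking),
                 best_pair = paste(x$best_pair, collapse = ":"),
                 j_resampled_best = x$ranking$j_resampled[1],
                 j_raw_best = x$ranking$j_raw[1])
}

#' Fisher linear decision boundary in a two-protein space
#'
#' The Fisher direction `w = (S_w + ridge I)^-1 (m_1 - m_2)` (class 1 = the
#' alphabetically first label), with the boundary offset placed at the
#' midpoint of the projected class means; `w` is normalised to unit length,
#' so the boundary is the line `w . x = c`. Swapping the class labels flips
#' the sign of `w` (and of `c`) but leaves the boundary set unchanged.
#'
#' @param x2 Samples-by-2 matrix (any feature count is accepted).
#' @param y Two class labels per row.
#' @param ridge Absolute ridge added to `S_w` (default 1e-8); if the scatter
#'   is degenerate the ridge is escalated with a warning.
#' @return List of class `decision_boundary`: `weights` (named, unit norm),
#'   `offset`, `classes` (`sign(w . x - c) > 0` on the first class's side).
#' @export
decision_boundary <- function(x2, y, ridge = 1e-8) {
  x2 <- as.matrix(x2)
  storage.mode(x2) <- "double"
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("need exactly two classes", call. = FALSE)
  sc <- class_scatter(x2, y)
  dm <- sc$class_means[1, ] - sc$class_means[2, ]
  d <- ncol(x2)
  solve_w <- function(lam) {
    tryCatch(solve(sc$sw + diag(lam, d), dm), error = function(e) NULL)
  }
  w <- solve_w(ridge)
  if (is.null(w)) {
    warning("degenerate within-class scatter; escalating ridge",
            call. = FALSE)
    w <- solve_w(ridge * 1e8 + 1e-12)
  }
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("class means coincide: no boundary direction",
                    call. = FALSE)
  w <- w / nw
  mid <- (sc$class_means[1, ] + sc$class_means[2, ]) / 2
  names(w) <- colnames(x2)
  structure(list(weights = w, offset = sum(w * mid), classes = classes),
            class = "decision_boundary")
}
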