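#' Principal component analysis of pooled tissue responses
#'
#' Column-mean-centered PCA (covariance, no unit-variance scaling: the
#' normalized differences already share the bounded [-1, 1] scale) of a
#' response matrix with both tissue states stacked. Component signs follow a
#' deterministic convention: the largest-magnitude loading of each component
#' is positive.
#'
#' @param data A response tibble from [build_response_matrix()] (annotation
#'   columns plus protein columns), or a plain numeric matrix.
#' @return Object of class `state_pca`: list with `scores` (tibble carrying
#'   the annotation columns plus `PC1..PCr`), `loadings` (proteins x
#'   components matrix), `explained_variance` (fractions, non-increasing)
#'   and `center`.
#' @export
state_pca <- function(data) {
  x <- as_protein_matrix(data)
  if (nrow(x) < 2) stop("need at least two rows", call. = FALSE)
  if (anyNA(x)) stop("response matrix contains missing values", call. = FALSE)
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  if (all(fit$sdev < 1e-12)) stop("constant matrix has no components",
                                  call. = FALSE)
  # sign convention: per component, the largest-|loading| element is positive
  flip <- apply(fit$rotation, 2, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  rot <- sweep(fit$rotation, 2, flip, `*`)
  scr <- sweep(fit$x, 2, flip, `*`)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  meta_names <- intersect(.meta_cols, names(as.data.frame(data)))
  scores <- if (is.data.frame(data)) {
    dplyr::bind_cols(data[, meta_names, drop = FALSE],
                     tibble::as_tibble(scr))
  } else {
    tibble::as_tibble(scr)
  }
  structure(list(scores = scores, loadings = rot, explained_variance = ev,
                 center = fit$center),
            class = "state_pca")
}

#' @export
print.state_pca <- function(x, ...) {
  ev <- round(100 * x$explained_variance[seq_len(min(4, length(
    x$explained_variance)))], 1)
  cat("PCA of", nrow(x$scores), "responses x", nrow(x$loadings),
      "proteins\n")
  cat("variance explained (%):", paste(ev, collapse = ", "),
      if (length(x$explained_variance) > 4) "..." else "", "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.state_pca <- function(x, ...) {
  tibble::tibble(
    protein = rep(rownames(x$loadings), ncol(x$loadings)),
    component = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.vector(x$loadings))
}

#' @exportS3Method generics::glance
glance.state_pca <- function(x, ...) {
  ev <- x$explained_variance
  tibble::tibble(
    n = nrow(x$scores),
    n_proteins = nrow(x$loadings),
    var_pc1 = ev[1],
    var_pc2 = if (length(ev) >= 2) ev[2] else NA_real_,
    var_first4 = sum(ev[seq_len(min(4, length(ev)))]))
}

#' Unsupervised tissue-state assignment by k-means on leading components
#'
#' Clusters the samples with k-means (k-means++-style multiple restarts via
#' `nstart`) on the first `n_dims` principal-component scores, then maps
#' clusters to tissue states by the majority of true labels within each
#' cluster (for k = 2 the accuracy-maximising bijection, which coincides
#' with per-cluster majority whenever that is consistent). An exact tie in
#' the majority vote is an error prompting manual mapping.
#'
#' @param pca A `state_pca` whose score table carries a `state` column.
#' @param n_dims Number of leading components clustered on (default 4).
#' @param k Number of clusters (default 2).
#' @param seed Optional integer making the restarts reproducible.
#' @param restarts `nstart` for [stats::kmeans()] (default 50).
#' @return Object of class `cluster_assignment`: list with `assignments`
#'   (tibble: annotation columns, `cluster`, `assigned_state`), `confusion`
#'   (true state x assigned state counts), `mapping`, `n_misassigned`
#'   (named per true state) and `tot_withinss`.
#' @export
cluster_states <- function(pca, n_dims = 4, k = 2, seed = NULL,
                           restarts = 50) {
  stopifnot(inherits(pca, "state_pca"))
  pcs <- grep("^PC", names(pca$scores), value = TRUE)
  if (n_dims > length(pcs)) {
    stop("n_dims exceeds available components", call. = FALSE)
  }
  if (!"state" %in% names(pca$scores)) {
    stop("score table has no 'state' column to map clusters against",
         call. = FALSE)
  }
  x <- as.matrix(pca$scores[, pcs[seq_len(n_dims)]])
  run <- function() kmeans(x, centers = k, nstart = restarts)
  km <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  truth <- pca$scores$state
  counts <- table(cluster = km$cluster, state = truth)
  states <- colnames(counts)
  if (k == 2 && length(states) == 2) {
    acc_id <- counts[1, 1] + counts[2, 2]
    acc_sw <- counts[1, 2] + counts[2, 1]
    if (acc_id == acc_sw) {
      stop("majority tie: cluster-to-state mapping is ambiguous, map manually",
           call. = FALSE)
    }
    mapping <- if (acc_id > acc_sw) states else rev(states)
    names(mapping) <- rownames(counts)
  } else {
    mapping <- apply(counts, 1, function(r) {
      top <- which(r == max(r))
      if (length(top) > 1) {
        stop("majority tie: cluster-to-state mapping is ambiguous, ",
             "map manually", call. = FALSE)
      }
      states[top]
    })
  }
  assigned <- unname(mapping[as.character(km$cluster)])
  confusion <- table(state = truth, assigned = factor(assigned,
                                                      levels = states))
  n_mis <- vapply(states, function(s) {
    sum(truth == s & assigned != s)
  }, integer(1))
  structure(list(
    assignments = dplyr::bind_cols(
      pca$scores[, setdiff(names(pca$scores), pcs), drop = FALSE],
      tibble::tibble(cluster = km$cluster, assigned_state = assigned)),
    confusion = confusion, mapping = mapping, n_misassigned = n_mis,
    tot_withinss = km$tot.withinss),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("k-means tissue-state assignment (", nrow(x$assignments),
      " samples)\n", sep = "")
  print(x$confusion)
  cat("misassigned:", paste(names(x$n_misassigned), x$n_misassigned,
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_assignment <- function(x, ...) {
  tb <- as.data.frame(x$confusion)
  tibble::tibble(state = tb$state, assigned = tb$assigned, n = tb$Freq)
}

#' @exportS3Method generics::glance
glance.cluster_assignment <- function(x, ...) {
  n <- nrow(x$assignments)
  mis <- sum(x$n_misassigned)
  tibble::tibble(n = n, n_misassigned = mis,
                 accuracy = 1 - mis / n,
                 tot_withinss = x$tot_withinss)
}

#' Ranked first-component loadings
#'
#' Reports the proteins ranked by the magnitude of their PC1 loading, with
#' signs, and annotates the direction convention: when the score table
#' carries true state labels, the report states which tissue state an
#' increasing PC1 score moves a response toward (the state with the larger
#' mean PC1 score).
#'
#' @param pca A `state_pca`.
#' @param top_n Optional number of top proteins to keep.
#' @return Tibble with columns `protein`, `loading`, `rank`; attribute
#'   `direction` describes the sign convention.
#' @export
pc1_loading_report <- function(pca, top_n = NULL) {
  stopifnot(inherits(pca, "state_pca"))
  w <- pca$loadings[, 1]
  out <- tibble::tibble(protein = names(w), loading = unname(w))
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$loading)))
  out$rank <- seq_len(nrow(out))
  if (!is.null(top_n)) out <- head(out, top_n)
  if ("state" %in% names(pca$scores)) {
    m <- tapply(pca$scores$PC1, pca$scores$state, mean)
    attr(out, "direction") <- paste0(
      "increasing PC1 score moves a response toward the '",
      names(m)[which.max(m)], "' cluster")
  }
  out
}
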