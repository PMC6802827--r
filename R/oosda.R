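# Class scatter matrices in the conventions used throughout: within-class
# scatter weights each class by 1/N_k; between-class scatter averages the
# squared deviations of class means from their unweighted grand mean (1/K).
class_scatter <- function(x, y) {
  classes <- sort(unique(as.character(y)))
  k_n <- length(classes)
  d <- ncol(x)
  mk <- matrix(0, k_n, d)
  sw <- matrix(0, d, d)
  for (i in seq_len(k_n)) {
    xi <- x[y == classes[i], , drop = FALSE]
    mk[i, ] <- colMeans(xi)
    sw <- sw + crossprod(sweep(xi, 2, mk[i, ])) / nrow(xi)
  }
  m <- colMeans(mk)
  sb <- crossprod(sweep(mk, 2, m)) / k_n
  list(classes = classes, class_means = mk, grand_mean = m, sw = sw, sb = sb)
}

#' Fit sequential Fisher-criterion orthonormal projections (OOS-DA)
#'
#' A multi-output generalisation of Fisher's linear discriminant: the first
#' direction maximises the Fisher quotient `w' S_b w / w' S_w w` over the
#' whole feature space; each subsequent direction maximises the same
#' quotient restricted to the orthogonal complement of the directions found
#' so far (solved as a generalized symmetric eigenproblem in an explicit
#' complement basis, which guarantees exact column orthonormality rather
#' than relying on Gram-Schmidt after the fact). The within-class scatter is
#' ridge-regularised by `ridge * trace(S_w)/d * I`, which keeps the
#' criterion well defined when there are fewer samples than features.
#'
#' @param data Response tibble (protein columns plus a `state` column used
#'   as labels), or a numeric samples-by-features matrix.
#' @param labels Class labels; taken from `data$state` when `data` is a
#'   response tibble and `labels` is `NULL`.
#' @param r Number of projection directions (default 2, at most the feature
#'   count).
#' @param ridge Relative ridge on `S_w` (default 1e-8).
#' @return Object of class `oosda`: list with `W` (features x r, orthonormal
#'   columns), `fisher_scores` (per column; the first is maximal), `classes`,
#'   `class_means`, `sw`, `sb` and `center`.
#' @export
fit_oosda <- function(data, labels = NULL, r = 2, ridge = 1e-8) {
  if (is.data.frame(data)) {
    labels <- labels %||% data$state
    x <- as_protein_matrix(data)
  } else {
    x <- as.matrix(data)
    storage.mode(x) <- "double"
  }
  if (is.null(labels)) stop("class labels required", call. = FALSE)
  y <- as.character(labels)
  if (length(unique(y)) < 2) stop("need at least two classes", call. = FALSE)
  if (any(table(y) < 2)) {
    stop("each class needs at least two samples", call. = FALSE)
  }
  d <- ncol(x)
  if (r > d) stop("r exceeds the feature count", call. = FALSE)
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sc <- class_scatter(xc, y)
  if (sum(diag(sc$sw)) + sum(diag(sc$sb)) < 1e-24) {
    stop("all samples identical: scatter is zero", call. = FALSE)
  }
  tr_sw <- sum(diag(sc$sw))
  lambda <- if (tr_sw > 0) ridge * tr_sw / d else ridge
  swr <- sc$sw + diag(lambda, d)
  W <- matrix(0, d, r)
  scores <- numeric(r)
  B <- diag(d)
  for (i in seq_len(r)) {
    sw_b <- crossprod(B, swr %*% B)
    sb_b <- crossprod(B, sc$sb %*% B)
    R <- chol((sw_b + t(sw_b)) / 2)
    Ri <- backsolve(R, diag(ncol(R)))
    M <- crossprod(Ri, sb_b %*% Ri)
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    u <- Ri %*% e$vectors[, 1]
    w <- as.vector(B %*% u)
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w  # reproducible sign
    W[, i] <- w
    scores[i] <- as.numeric(crossprod(w, sc$sb %*% w) /
                              crossprod(w, swr %*% w))
    if (i < r) {
      Q <- qr.Q(qr(W[, seq_len(i), drop = FALSE]), complete = TRUE)
      B <- Q[, (i + 1):d, drop = FALSE]
    }
  }
  rownames(W) <- colnames(x)
  colnames(W) <- paste0("OOS", seq_len(r))
  structure(list(W = W, fisher_scores = scores, classes = sc$classes,
                 class_means = sc$class_means, sw = sc$sw, sb = sc$sb,
                 center = center),
            class = "oosda")
}

#' Project samples onto fitted discriminant directions
#'
#' @param object An `oosda` fit.
#' @param newdata Response tibble or numeric matrix with the same features
#'   the model was fitted on.
#' @param ... Unused.
#' @return Tibble of projection scores `OOS1..OOSr`, with the annotation
#'   columns of `newdata` carried along when present.
#' @export
predict.oosda <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    x <- as_protein_matrix(newdata)
    meta <- newdata[, intersect(.meta_cols, names(newdata)), drop = FALSE]
  } else {
    x <- as.matrix(newdata)
    meta <- NULL
  }
  if (ncol(x) != nrow(object$W)) {
    stop("feature count does not match the fitted model", call. = FALSE)
  }
  scores <- sweep(x, 2, object$center) %*% object$W
  out <- tibble::as_tibble(scores)
  if (!is.null(meta) && ncol(meta) > 0) out <- dplyr::bind_cols(meta, out)
  out
}

#' @export
print.oosda <- function(x, ...) {
  cat("OOS-DA fit:", nrow(x$W), "features,", ncol(x$W),
      "orthonormal discriminant direction(s)\n")
  cat("Fisher scores:", paste(signif(x$fisher_scores, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.oosda <- function(x, ...) {
  tibble::tibble(
    protein = rep(rownames(x$W), ncol(x$W)),
    component = rep(colnames(x$W), each = nrow(x$W)),
    weight = as.vector(x$W))
}

#' @exportS3Method generics::glance
glance.oosda <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$W), r = ncol(x$W),
                 fisher_1 = x$fisher_scores[1],
                 n_classes = length(x$classes))
}
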