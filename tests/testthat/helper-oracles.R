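# Independent brute-force oracles, deliberately written as literal loops over
# the defining sums so they share no code with the package internals.

# Within/between spreads and their ratio, term by term.
oracle_separation <- function(x, y) {
  x <- as.matrix(x)
  classes <- sort(unique(as.character(y)))
  k_n <- length(classes)
  means <- list()
  s_w <- 0
  for (k in seq_len(k_n)) {
    xk <- x[as.character(y) == classes[k], , drop = FALSE]
    m <- colSums(xk) / nrow(xk)
    means[[k]] <- m
    acc <- 0
    for (n in seq_len(nrow(xk))) {
      acc <- acc + sum((xk[n, ] - m)^2)
    }
    s_w <- s_w + acc / nrow(xk)
  }
  grand <- Reduce(`+`, means) / k_n
  s_b <- 0
  for (k in seq_len(k_n)) {
    s_b <- s_b + sum((means[[k]] - grand)^2) / k_n
  }
  list(s_w = s_w, s_b = s_b, j = s_b / s_w)
}

# All-pairs-distance nearest-neighbour imputation: distance over mutually
# observed coordinates scaled by sqrt(p / n_shared), ties by row index.
oracle_impute <- function(x, k = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  out <- x
  for (r in seq_len(n)) {
    for (j in seq_len(p)) {
      if (!is.na(x[r, j])) next
      cand <- integer(0)
      dist <- numeric(0)
      for (s in seq_len(n)) {
        if (s == r || is.na(x[s, j])) next
        shared <- which(!is.na(x[r, ]) & !is.na(x[s, ]))
        d <- if (length(shared) == 0) Inf else
          sqrt(sum((x[r, shared] - x[s, shared])^2) * p / length(shared))
        cand <- c(cand, s)
        dist <- c(dist, d)
      }
      ord <- order(dist, cand)
      take <- cand[ord][seq_len(min(k, length(cand)))]
      out[r, j] <- mean(x[take, j])
    }
  }
  out
}

# Closed-form Fisher discriminant direction for two classes, using the same
# 1/N_k within-scatter convention as the separation criterion.
oracle_lda_direction <- function(x, y) {
  x <- as.matrix(x)
  classes <- sort(unique(as.character(y)))
  stopifnot(length(classes) == 2)
  x1 <- x[y == classes[1], , drop = FALSE]
  x2 <- x[y == classes[2], , drop = FALSE]
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  sw <- crossprod(sweep(x1, 2, m1)) / nrow(x1) +
    crossprod(sweep(x2, 2, m2)) / nrow(x2)
  solve(sw + diag(1e-10, ncol(x)), m1 - m2)
}

abs_cosine <- function(a, b) {
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}

# Two-sided pooled-variance t-test computed from first principles.
oracle_t_pvalue <- function(x1, x2) {
  n1 <- length(x1)
  n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(t), df = n1 + n2 - 2)
}

# Small reusable fixtures -----------------------------------------------------

tiny_design <- function() {
  build_stimulus_panel(c("A1", "A2"), c("B1", "B2", "B3"))
}

# A noise-free generator over a small panel that includes two stimulating
# proteins, so self-channel saturation is exercised.
tiny_config <- function(cv = 0, ...) {
  generator_config(proteins = c("A1", "B1", "X", "Y", "Z"),
                   baseline_median = c(1000, 2000, 500, 4000, 800),
                   cv = cv, blank_level = 50, saturation_ceiling = 32000,
                   ...)
}

# Random two-class Gaussian problem with anisotropic shared covariance.
gaussian_problem <- function(seed, n = 30, d = 5, gap = 2) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(d * d), d)
    sigma <- chol(crossprod(a) / d + diag(0.5, d))
    mu <- rnorm(d) * gap / sqrt(d)
    x <- rbind(matrix(rnorm(n * d), n) %*% sigma,
               sweep(matrix(rnorm(n * d), n) %*% sigma, 2, -mu))
    list(x = x, y = rep(c("a", "b"), each = n))
  })
}

table3_effects <- c(IL4 = 5.7, TFF3 = 5.2, IFNG = 4.2, PEDF = -3.2,
                    TNFa = 3.1, CCL5 = 3.0, IL13 = 2.6, S100A6 = 2.4,
                    CXCL11 = 2.3, IL17F = 1.4, TNFSF12 = 1.3)

# Recovery criterion for planted baseline shifts: every planted protein is
# retained at the significance threshold AND the planted set occupies the
# top-|planted| ranks when all proteins are ordered by |d|.
recovers_planted <- function(result, planted) {
  all_tbl <- attr(result, "all")
  by_mag <- all_tbl$protein[order(-abs(all_tbl$cohens_d))]
  all(planted %in% result$protein) &&
    setequal(by_mag[seq_along(planted)], planted)
}
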