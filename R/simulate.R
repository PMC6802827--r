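#' Generator configuration for synthetic multiplex plates
#'
#' Bundles the parameters of the synthetic plate model. Well-level MFIs are
#' drawn from lognormal distributions parameterised by their median and a
#' coefficient of variation on the natural scale (multiplicative noise: MFI
#' data are positive and right-skewed), then clipped to the instrument range.
#'
#' @param proteins Character vector of measured protein names.
#' @param baseline_median Positive numeric, recycled over proteins: median
#'   unstimulated MFI per protein.
#' @param cv Replicate coefficient of variation (sd/mean on the natural
#'   scale), recycled over proteins. Typical bead-array assays sit at
#'   0.10-0.25; default 0.15.
#' @param blank_level Mean blank (reagent-only) MFI, recycled over proteins.
#' @param detection_floor,saturation_ceiling Instrument range in MFI units;
#'   simulated values are clipped into `[detection_floor,
#'   saturation_ceiling]`.
#' @param batch_scale Log-sd of one multiplicative lognormal factor drawn
#'   per plate (plate/patient batch effect); 0 disables it.
#' @param n_blanks Number of duplicate blank wells per plate.
#' @param effects Tibble with columns `tissue_state`, `stimulus_id`,
#'   `protein`, `factor`: multiplicative response factors applied to the
#'   baseline median of stimulated wells. `"*"` in `tissue_state` or
#'   `stimulus_id` is a wildcard; matching rows multiply together. Control
#'   wells always use factor 1.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(proteins = cytokine_panel(),
                             baseline_median = 2000,
                             cv = 0.15,
                             blank_level = 50,
                             detection_floor = 0,
                             saturation_ceiling = 32000,
                             batch_scale = 0,
                             n_blanks = 2,
                             effects = NULL) {
  proteins <- as.character(proteins)
  baseline_median <- rep_len(as.numeric(baseline_median), length(proteins))
  cv <- rep_len(as.numeric(cv), length(proteins))
  blank_level <- rep_len(as.numeric(blank_level), length(proteins))
  names(baseline_median) <- names(cv) <- names(blank_level) <- proteins
  if (any(cv < 0)) stop("cv must be >= 0", call. = FALSE)
  if (any(blank_level < 0)) stop("blank_level must be >= 0", call. = FALSE)
  if (any(baseline_median <= blank_level)) {
    stop("baseline_median must exceed blank_level for every protein",
         call. = FALSE)
  }
  if (saturation_ceiling <= max(baseline_median)) {
    stop("saturation_ceiling must exceed all baseline medians", call. = FALSE)
  }
  if (is.null(effects)) {
    effects <- tibble::tibble(tissue_state = character(),
                              stimulus_id = character(),
                              protein = character(),
                              factor = numeric())
  }
  stopifnot(all(c("tissue_state", "stimulus_id", "protein", "factor")
                %in% names(effects)))
  structure(
    list(proteins = proteins, baseline_median = baseline_median, cv = cv,
         blank_level = blank_level, detection_floor = detection_floor,
         saturation_ceiling = saturation_ceiling, batch_scale = batch_scale,
         n_blanks = n_blanks, effects = tibble::as_tibble(effects)),
    class = "generator_config")
}

#' Default generator with structured stimulus responses
#'
#' Builds a `generator_config` emulating the statistical structure the
#' downstream analysis assumes: per-protein baselines spread log-uniformly
#' over the assay's working range, a low-rank latent response structure
#' (stimuli engage correlated protein programmes, which is what gives real
#' response matrices a few dominant principal components) plus independent
#' per-(stimulus, protein) heterogeneity, and an optional per-protein
#' modulation of the degrading state's responses so the two states differ
#' broadly, not only in a planted pair.
#'
#' @param design A `stimulus_design`; response factors are drawn for its
#'   stimuli.
#' @param proteins Measured panel.
#' @param seed Integer seed used (locally) to draw baselines and response
#'   factors; the same seed reproduces the same configuration.
#' @param baseline_range Length-2 numeric, MFI range the per-protein
#'   baseline medians are log-uniformly drawn from.
#' @param n_latent Number of latent response programmes.
#' @param latent_scale Scale of latent loadings on the log-response.
#' @param heterogeneity_sd Log-sd of independent per-(stimulus, protein)
#'   response noise shared by both states.
#' @param state_modulation_sd Log-sd of a per-protein factor applied to the
#'   degrading state's responses (0 makes the two states exchangeable).
#' @param cv,blank_level,saturation_ceiling,batch_scale Passed to
#'   [generator_config()].
#' @return A `generator_config`.
#' @export
default_generator_config <- function(design,
                                     proteins = cytokine_panel(),
                                     seed = 1,
                                     baseline_range = c(500, 20000),
                                     n_latent = 3,
                                     latent_scale = 0.25,
                                     heterogeneity_sd = 0.3,
                                     state_modulation_sd = 0.3,
                                     cv = 0.15,
                                     blank_level = 50,
                                     saturation_ceiling = 32000,
                                     batch_scale = 0) {
  withr::with_seed(seed, {
    p <- length(proteins)
    s <- nrow(design)
    baselines <- exp(runif(p, log(baseline_range[1]), log(baseline_range[2])))
    # log-response = latent programmes + iid heterogeneity, shared across
    # states (wildcard "*"); the degrading state gets an extra per-protein
    # modulation so states differ along a diffuse direction.
    u <- matrix(rnorm(s * n_latent), s, n_latent)
    v <- matrix(rnorm(p * n_latent, sd = latent_scale), n_latent, p)
    log_g <- u %*% v + matrix(rnorm(s * p, sd = heterogeneity_sd), s, p)
    shared <- tibble::tibble(
      tissue_state = "*",
      stimulus_id = rep(design$stimulus_id, times = p),
      protein = rep(proteins, each = s),
      factor = exp(as.vector(log_g)))
    eff <- shared
    if (state_modulation_sd > 0) {
      eff <- dplyr::bind_rows(eff, tibble::tibble(
        tissue_state = "degrading",
        stimulus_id = "*",
        protein = proteins,
        factor = exp(rnorm(p, sd = state_modulation_sd))))
    }
    generator_config(proteins = proteins, baseline_median = baselines,
                     cv = cv, blank_level = blank_level,
                     saturation_ceiling = saturation_ceiling,
                     batch_scale = batch_scale, effects = eff)
  })
}

#' Plant a discriminative protein pair into a generator
#'
#' Adds opposite, state-antisymmetric response shifts for two measured
#' proteins so that, in expectation, the healthy and degrading states differ
#' in the planted pair (on top of whatever the configuration already
#' contains). Protein `pair[i]` responds with factor `2^shift[i]` in healthy
#' tissue and `2^(-shift[i])` in degrading tissue, for every stimulus. With
#' opposite-sign shifts this emulates the joint pattern where one protein's
#' release rises on stimulation in healthy tissue while falling in degrading
#' tissue and its partner does the reverse.
#'
#' @param config A `generator_config`.
#' @param pair Character vector of two measured protein names.
#' @param shift Numeric length 2: signed log2 response shifts; 0 leaves the
#'   configuration unchanged in distribution.
#' @return A new `generator_config`.
#' @export
plant_discriminative_pair <- function(config, pair = c("MMP9", "IFNG"),
                                      shift = c(1.5, -1.5)) {
  stopifnot(inherits(config, "generator_config"), length(pair) == 2)
  shift <- rep_len(as.numeric(shift), 2)
  missing_p <- setdiff(pair, config$proteins)
  if (length(missing_p) > 0) {
    stop("planted protein(s) not in measured panel: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  extra <- tibble::tibble(
    tissue_state = rep(c("healthy", "degrading"), each = 2),
    stimulus_id = "*",
    protein = rep(pair, 2),
    factor = c(2^shift, 2^(-shift)))
  config$effects <- dplyr::bind_rows(config$effects, extra)
  config
}

# Multiplicative response-factor matrix (stimuli x proteins) for one state.
effect_matrix <- function(config, design, state) {
  s <- nrow(design)
  proteins <- config$proteins
  E <- matrix(1, s, length(proteins),
              dimnames = list(design$stimulus_id, proteins))
  eff <- config$effects
  if (nrow(eff) == 0) return(E)
  eff <- eff[eff$tissue_state %in% c("*", state), , drop = FALSE]
  if (nrow(eff) == 0) return(E)
  bad <- setdiff(unique(eff$protein), proteins)
  if (length(bad) > 0) {
    stop("effect map references unknown protein(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  specific <- eff$stimulus_id != "*"
  if (any(specific)) {
    es <- eff[specific, , drop = FALSE]
    ri <- match(es$stimulus_id, design$stimulus_id)
    if (anyNA(ri)) {
      stop("effect map references unknown stimulus id(s): ",
           paste(unique(es$stimulus_id[is.na(ri)]), collapse = ", "),
           call. = FALSE)
    }
    ci <- match(es$protein, proteins)
    idx <- cbind(ri, ci)
    for (r in seq_len(nrow(es))) {
      E[idx[r, 1], idx[r, 2]] <- E[idx[r, 1], idx[r, 2]] * es$factor[r]
    }
  }
  wild <- eff[!specific, , drop = FALSE]
  for (r in seq_len(nrow(wild))) {
    ci <- match(wild$protein[r], proteins)
    E[, ci] <- E[, ci] * wild$factor[r]
  }
  E
}

#' Simulate one multiplex plate
#'
#' Draws a full plate for one tissue state: one well per stimulus of the
#' design, one unstimulated control well, and duplicate blank wells. Each
#' stimulated well's protein channel is lognormal with median
#' `baseline_median * effect(state, stimulus, protein) * plate_batch_factor`
#' and the configured CV, clipped to the instrument range; the channel(s) of
#' a well's own stimulating protein(s) are then forced to the saturation
#' ceiling (an antibody-sandwich assay cannot distinguish the added
#' recombinant stimulus from tissue release, so the self-channel rails).
#' Control wells use effect 1; blank wells are lognormal around the blank
#' level with tissue state `"none"`.
#'
#' @param config A `generator_config`.
#' @param design A `stimulus_design`.
#' @param state `"healthy"` or `"degrading"`.
#' @param plate_id Plate identifier stamped on every well.
#' @param seed Optional integer; when given, the draw is made under a local
#'   RNG state so runs are bit-reproducible.
#' @return An MFI table: tibble with columns `plate_id`, `well_id`,
#'   `tissue_state`, `stimulus_id` and one column per protein.
#' @export
#' @examples
#' g <- stimulus_groups()
#' d <- build_stimulus_panel(g$pro_catabolic[1:2], g$anti_anabolic[1:2])
#' cfg <- generator_config(proteins = c("IFNG", "MMP9"), baseline_median = 1000)
#' simulate_plate(cfg, d, "healthy", seed = 1)
simulate_plate <- function(config, design, state, plate_id = "P1",
                           seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!state %in% c("healthy", "degrading")) {
    stop("unknown tissue state: ", state, call. = FALSE)
  }
  draw <- function() {
    proteins <- config$proteins
    p <- length(proteins)
    s <- nrow(design)
    sdlog <- sqrt(log1p(config$cv^2))  # per protein
    batch <- if (config$batch_scale > 0) {
      exp(rnorm(1, sd = config$batch_scale))
    } else 1
    E <- effect_matrix(config, design, state)
    med <- sweep(E, 2, config$baseline_median, `*`) * batch
    noise <- matrix(rnorm(s * p), s, p) %*% diag(sdlog, p)
    vals <- med * exp(noise)
    ctrl <- config$baseline_median * batch *
      exp(rnorm(p) * sdlog)
    blanks <- matrix(config$blank_level, config$n_blanks, p, byrow = TRUE) *
      exp(matrix(rnorm(config$n_blanks * p), config$n_blanks, p) %*%
            diag(sdlog, p))
    clip <- function(m) {
      pmin(pmax(m, config$detection_floor), config$saturation_ceiling)
    }
    vals <- clip(vals)
    ctrl <- clip(ctrl)
    blanks <- clip(blanks)
    # self-channel saturation, applied after noise and clipping
    for (i in seq_len(s)) {
      members <- intersect(c(design$protein_1[i], design$protein_2[i]),
                           proteins)
      vals[i, match(members, proteins)] <- config$saturation_ceiling
    }
    all_vals <- rbind(vals, ctrl, blanks)
    out <- tibble::tibble(
      plate_id = plate_id,
      well_id = c(sprintf("S%02d", seq_len(s)), "control",
                  paste0("blank", seq_len(config$n_blanks))),
      tissue_state = c(rep(state, s + 1), rep("none", config$n_blanks)),
      stimulus_id = c(design$stimulus_id, "control",
                      rep("blank", config$n_blanks)))
    out[proteins] <- as.data.frame(all_vals)
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a baseline-release comparison experiment
#'
#' Generates raw MFI wells for an unstimulated control group and a treated
#' group, with planted standardized mean differences per protein. The
#' treated median factor `f` is calibrated so the expected raw-scale pooled
#' Cohen's d equals the requested value: because the multiplicative noise
#' makes each group's sd proportional to its mean, `f` solves
#' `f - 1 = d * cv * sqrt(((n_t - 1) f^2 + (n_c - 1)) / (n_t + n_c - 2))`
#' (fixed-point iteration).
#'
#' @param config A `generator_config` supplying proteins, baselines and cv.
#' @param n_control,n_treated Wells per group.
#' @param d Named numeric vector of planted Cohen's d values (proteins
#'   absent from it are unshifted).
#' @param seed Optional integer for a local, reproducible draw.
#' @return List with elements `control` and `treated`, each an MFI table.
#' @export
simulate_baseline_release <- function(config, n_control = 3, n_treated = 6,
                                      d = numeric(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  bad <- setdiff(names(d), config$proteins)
  if (length(bad) > 0) {
    stop("planted protein(s) not in panel: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  draw <- function() {
    proteins <- config$proteins
    p <- length(proteins)
    sdlog <- sqrt(log1p(config$cv^2))
    shift <- rep(0, p)
    names(shift) <- proteins
    shift[names(d)] <- d
    # calibrate the median factor so the expected pooled Cohen's d is the
    # planted value despite the sd scaling with the treated mean
    fac <- mapply(function(di, cvi) {
      f <- 1
      for (it in 1:50) {
        f <- 1 + di * cvi *
          sqrt(((n_treated - 1) * f^2 + (n_control - 1)) /
                 (n_treated + n_control - 2))
        if (f <= 0) {
          stop("planted effect too negative for the configured cv",
               call. = FALSE)
        }
      }
      f
    }, shift, config$cv[proteins])
    one_group <- function(n, medians, label) {
      m <- matrix(medians, n, p, byrow = TRUE) *
        exp(matrix(rnorm(n * p), n, p) %*% diag(sdlog, p))
      m <- pmin(pmax(m, config$detection_floor), config$saturation_ceiling)
      out <- tibble::tibble(
        plate_id = label, well_id = sprintf("%s%02d", label, seq_len(n)),
        tissue_state = "healthy", stimulus_id = "control")
      out[proteins] <- as.data.frame(m)
      out
    }
    list(control = one_group(n_control, config$baseline_median, "CTRL"),
         treated = one_group(n_treated, config$baseline_median * fac, "TRT"))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
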