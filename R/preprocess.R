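#' Mask measurements below the blank background
#'
#' For each plate and protein, the arithmetic mean of that plate's blank
#' wells defines the background; measurement-well MFIs strictly below it are
#' set to missing (they carry no signal above experimental noise). Blank
#' rows themselves are left untouched.
#'
#' @param data An MFI table (see [simulate_plate()] for the dialect).
#' @return The table with below-background entries replaced by `NA`.
#' @export
mask_below_blank <- function(data) {
  proteins <- protein_cols(data)
  for (p in unique(data$plate_id)) {
    on_plate <- data$plate_id == p
    blank <- on_plate & data$stimulus_id == "blank"
    if (!any(blank)) {
      stop("no blank wells on plate ", p, call. = FALSE)
    }
    thr <- colMeans(data[blank, proteins, drop = FALSE], na.rm = TRUE)
    meas <- which(on_plate & !blank)
    for (j in proteins) {
      v <- data[[j]][meas]
      v[!is.na(v) & v < thr[[j]]] <- NA_real_
      data[[j]][meas] <- v
    }
  }
  data
}

#' Mask the saturated self-channels of stimulated wells
#'
#' A well stimulated with a recombinant protein reads out saturated on that
#' protein's own channel (the assay cannot separate the spiked-in stimulus
#' from tissue release), so the channel(s) of each well's stimulating
#' protein(s) are set to missing -- both channels for pair stimuli. Control
#' and blank wells are untouched; stimulating proteins not in the measured
#' panel have no channel to mask.
#'
#' @param data An MFI table.
#' @param design The `stimulus_design` the wells' `stimulus_id`s refer to.
#' @return The table with self-channels replaced by `NA`.
#' @export
mask_saturated_self_channels <- function(data, design) {
  proteins <- protein_cols(data)
  stim_rows <- which(!data$stimulus_id %in% c("control", "blank"))
  unknown <- setdiff(data$stimulus_id[stim_rows], design$stimulus_id)
  if (length(unknown) > 0) {
    stop("stimulus id(s) not in design: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  idx <- match(data$stimulus_id[stim_rows], design$stimulus_id)
  for (k in seq_along(stim_rows)) {
    members <- intersect(c(design$protein_1[idx[k]], design$protein_2[idx[k]]),
                         proteins)
    for (j in members) data[[j]][stim_rows[k]] <- NA_real_
  }
  data
}

#' Nearest-neighbour imputation of a rows-by-proteins matrix
#'
#' Each missing entry (r, j) is replaced by the mean of column j over the k
#' nearest rows that observe j. Row distance is Euclidean over the
#' coordinates observed in both rows, scaled by `sqrt(n_total/n_observed)`
#' so distances are comparable across missingness patterns; ties are broken
#' by row order. Rows with no mutually observed coordinate are at infinite
#' distance and are only used as a last resort (again in row order).
#'
#' @param x Numeric matrix (or data frame of numerics) with `NA`s; every
#'   row and every column must have at least one observed entry and there
#'   must be at least two rows.
#' @param k Number of neighbours averaged (default 1).
#' @return The completed matrix, with a logical attribute `imputed` marking
#'   the entries that were filled in.
#' @export
#' @examples
#' m <- rbind(c(1, 2, NA), c(1, 2, 7), c(9, 9, 0))
#' impute_missing(m)[1, 3]  # 7, copied from the nearest row
impute_missing <- function(x, k = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2) stop("need at least two rows to impute", call. = FALSE)
  obs <- !is.na(x)
  if (any(colSums(obs) == 0)) {
    stop("column(s) missing in all rows: ",
         paste(which(colSums(obs) == 0), collapse = ", "), call. = FALSE)
  }
  if (any(rowSums(obs) == 0)) {
    stop("row(s) with no observed entry", call. = FALSE)
  }
  imputed <- !obs
  if (!any(imputed)) {
    attr(x, "imputed") <- imputed
    return(x)
  }
  dist_to <- function(r) {
    d <- rep(Inf, n)
    for (s in seq_len(n)[-r]) {
      shared <- obs[r, ] & obs[s, ]
      m <- sum(shared)
      if (m > 0) {
        d[s] <- sqrt(sum((x[r, shared] - x[s, shared])^2) * p / m)
      }
    }
    d
  }
  out <- x
  for (r in which(rowSums(imputed) > 0)) {
    d <- dist_to(r)
    for (j in which(imputed[r, ])) {
      cand <- which(obs[, j])
      cand <- cand[order(d[cand], cand)]
      take <- cand[seq_len(min(k, length(cand)))]
      out[r, j] <- mean(x[take, j])
    }
  }
  attr(out, "imputed") <- imputed
  out
}

#' Bounded normalized difference of a measurement against its control
#'
#' `(F - F_c) / (F + F_c)`: a symmetric, bounded fold-change surrogate that
#' maps equal signal to 0 and the strong-response limits to +1 / -1, making
#' responses comparable across proteins and plates.
#'
#' @param f Non-negative MFI of the stimulated well.
#' @param f_c Non-negative MFI of the matched unstimulated control.
#'   Vectorised with recycling.
#' @return Numeric in `[-1, +1]`.
#' @export
#' @examples
#' normalize_difference(3, 1)   # 0.5
#' normalize_difference(5, 5)   # 0
normalize_difference <- function(f, f_c) {
  if (any(f < 0, na.rm = TRUE) || any(f_c < 0, na.rm = TRUE)) {
    stop("MFIs must be non-negative", call. = FALSE)
  }
  s <- f + f_c
  if (any(s == 0, na.rm = TRUE)) {
    stop("normalized difference undefined where F + F_c = 0", call. = FALSE)
  }
  (f - f_c) / s
}

#' Build the normalized response matrix from raw plates
#'
#' Runs the plate-level post-processing chain on raw MFI tables, per
#' (plate, tissue state) block: below-blank masking, saturated self-channel
#' masking, nearest-neighbour imputation of the raw MFIs (stimulated wells
#' and the control well together), then the normalized difference of every
#' stimulated well against that block's control well. Imputation acts on raw
#' MFIs, before normalization, so the bounded transform always sees positive
#' values.
#'
#' @param data One or more plates as an MFI table.
#' @param design The `stimulus_design`; output rows follow its stimulus
#'   ordering within each block.
#' @param k Neighbour count for [impute_missing()].
#' @return A tibble with columns `state`, `stimulus_id`, `plate_id` and one
#'   column per protein, all entries in `[-1, +1]`; attribute `imputed` is a
#'   logical matrix marking entries that were masked (below-blank or
#'   self-channel) and filled by imputation before normalization.
#' @export
build_response_matrix <- function(data, design, k = 1) {
  proteins <- protein_cols(data)
  masked <- mask_below_blank(data)
  masked <- mask_saturated_self_channels(masked, design)
  blocks <- dplyr::distinct(
    dplyr::filter(masked, .data$tissue_state != "none"),
    .data$plate_id, .data$tissue_state)
  rows <- list()
  imp <- list()
  for (b in seq_len(nrow(blocks))) {
    pl <- blocks$plate_id[b]
    st <- blocks$tissue_state[b]
    block <- masked[masked$plate_id == pl & masked$tissue_state == st, ]
    ctrl_i <- which(block$stimulus_id == "control")
    if (length(ctrl_i) != 1) {
      stop("expected exactly one control well for plate ", pl, ", state ",
           st, "; found ", length(ctrl_i), call. = FALSE)
    }
    stim <- block[block$stimulus_id != "control", ]
    ord <- match(design$stimulus_id, stim$stimulus_id)
    ord <- ord[!is.na(ord)]
    stim <- stim[ord, ]
    raw <- rbind(as_protein_matrix(stim, proteins),
                 as_protein_matrix(block[ctrl_i, ], proteins))
    if (anyNA(raw)) {
      raw <- impute_missing(raw, k = k)
      mask <- attr(raw, "imputed")
    } else {
      mask <- matrix(FALSE, nrow(raw), ncol(raw))
    }
    nc <- nrow(raw)
    f_c <- raw[nc, ]
    d <- sweep(raw[-nc, , drop = FALSE], 2, f_c,
               function(f, fc) (f - fc) / (f + fc))
    if (any(!is.finite(d)) || any(abs(d) > 1 + 1e-12)) {
      stop("normalized differences out of [-1, 1] for plate ", pl,
           call. = FALSE)
    }
    out <- tibble::tibble(state = st, stimulus_id = stim$stimulus_id,
                          plate_id = pl)
    out[proteins] <- as.data.frame(d)
    rows[[b]] <- out
    imp[[b]] <- mask[-nc, , drop = FALSE]
  }
  res <- dplyr::bind_rows(rows)
  attr(res, "imputed") <- do.call(rbind, imp)
  attr(res, "proteins") <- proteins
  res
}

#' Assay precision report across replicate plates
#'
#' Matches wells across replicate MFI tables by (tissue state, stimulus) and
#' computes, per protein, the replicate coefficient of variation (sample
#' sd / mean, n-1 denominator) averaged over matched conditions, alongside
#' the mean blank level. Proteins whose CV reaches the flag threshold are
#' marked as failing the precision criterion.
#'
#' @param replicate_tables List of two or more MFI tables measuring the same
#'   conditions.
#' @param flag_threshold CV at or above which a protein is flagged
#'   (default 0.25).
#' @return A tibble with columns `protein`, `blank_mean`, `cv`,
#'   `n_conditions`, `flagged`.
#' @export
assay_cv <- function(replicate_tables, flag_threshold = 0.25) {
  if (!is.list(replicate_tables) || length(replicate_tables) < 2) {
    stop("need at least two replicate tables", call. = FALSE)
  }
  all <- dplyr::bind_rows(replicate_tables, .id = ".rep")
  proteins <- protein_cols(all[setdiff(names(all), ".rep")])
  meas <- all[all$stimulus_id != "blank", ]
  long <- tidyr::pivot_longer(meas, dplyr::all_of(proteins),
                              names_to = "protein", values_to = "mfi")
  per_cond <- dplyr::summarise(
    dplyr::group_by(long, .data$tissue_state, .data$stimulus_id,
                    .data$protein),
    n = sum(!is.na(.data$mfi)),
    cv = sd(.data$mfi, na.rm = TRUE) / mean(.data$mfi, na.rm = TRUE),
    .groups = "drop")
  if (any(per_cond$n < 2)) {
    stop("fewer than two replicates for some conditions", call. = FALSE)
  }
  blanks <- all[all$stimulus_id == "blank", ]
  blank_mean <- colMeans(blanks[, proteins, drop = FALSE], na.rm = TRUE)
  rep_cv <- dplyr::summarise(
    dplyr::group_by(per_cond, .data$protein),
    cv = mean(.data$cv), n_conditions = dplyr::n(), .groups = "drop")
  out <- tibble::tibble(protein = proteins,
                        blank_mean = unname(blank_mean[proteins]))
  out <- dplyr::left_join(out, rep_cv, by = "protein")
  out$flagged <- out$cv >= flag_threshold
  out
}
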