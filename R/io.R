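read_delim_sniffed <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (lengths(regmatches(first, gregexpr("\t", first))) >
               lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  readr::read_delim(path, delim = delim, na = c("", "NA"),
                    show_col_types = FALSE, progress = FALSE)
}

#' Read an MFI plate table
#'
#' Reads the delimited well-level dialect (comma or tab, sniffed from the
#' header line): annotation columns `plate_id`, `well_id`, `tissue_state`,
#' `stimulus_id`, then one numeric column per protein. `"NA"` and empty
#' cells are missing.
#'
#' @param path File path.
#' @return MFI tibble.
#' @export
read_mfi_table <- function(path) {
  tb <- read_delim_sniffed(path)
  required <- c("plate_id", "well_id", "tissue_state", "stimulus_id")
  miss <- setdiff(required, names(tb))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  proteins <- setdiff(names(tb), .meta_cols)
  bad_num <- proteins[!vapply(tb[proteins], is.numeric, logical(1))]
  if (length(bad_num) > 0) {
    stop("non-numeric MFI column(s): ", paste(bad_num, collapse = ", "),
         call. = FALSE)
  }
  bad_state <- which(!tb$tissue_state %in% c("healthy", "degrading", "none"))
  if (length(bad_state) > 0) {
    stop("unknown tissue state token at row(s): ",
         paste(head(bad_state, 10), collapse = ", "), call. = FALSE)
  }
  tb
}

#' Write an MFI plate table
#'
#' @param data MFI tibble.
#' @param path Output path (CSV, `NA` for missing values).
#' @return `data`, invisibly.
#' @export
write_mfi_table <- function(data, path) {
  readr::write_csv(data, path, na = "NA")
  invisible(data)
}

#' Write a normalized response matrix
#'
#' @param data Response tibble from [build_response_matrix()].
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_response_matrix <- function(data, path) {
  readr::write_csv(data, path, na = "NA")
  invisible(data)
}

#' Read a normalized response matrix
#'
#' Accepts both this package's response dialect (`state`, `stimulus_id`,
#' `plate_id` columns first) and a supplementary-table-style wide export:
#' stimuli rows by protein columns, optionally with a state column; when the
#' export holds one state block only, pass it via `state`. Values are
#' validated to the normalized-difference range `[-1, +1]`; 55 stimuli per
#' state are expected and a deviation warns.
#'
#' @param path File path of the delimited export.
#' @param state Tissue state assigned to the rows when the file has no
#'   state column.
#' @return Response tibble with columns `state`, `stimulus_id` (and
#'   `plate_id` when present) plus protein columns.
#' @export
read_s1_matrix <- function(path, state = NULL) {
  tb <- read_delim_sniffed(path)
  names(tb)[names(tb) == "tissue_state"] <- "state"
  if (!"state" %in% names(tb)) {
    if (is.null(state)) {
      stop("export has no state column; supply `state`", call. = FALSE)
    }
    tb <- dplyr::mutate(tb, state = state, .before = 1)
  }
  if (!"stimulus_id" %in% names(tb)) {
    first_chr <- names(tb)[vapply(tb, is.character, logical(1))]
    first_chr <- setdiff(first_chr, "state")
    if (length(first_chr) == 0) {
      stop("export has no stimulus identifier column", call. = FALSE)
    }
    names(tb)[names(tb) == first_chr[1]] <- "stimulus_id"
  }
  proteins <- setdiff(names(tb), .meta_cols)
  for (j in proteins) {
    bad <- which(!is.na(tb[[j]]) & abs(tb[[j]]) > 1)
    if (length(bad) > 0) {
      stop("value out of [-1, 1] at row ", bad[1], ", column '", j, "': ",
           tb[[j]][bad[1]], call. = FALSE)
    }
  }
  counts <- table(tb$state)
  if (any(counts != 55)) {
    warning("expected 55 stimuli per state; found ",
            paste(names(counts), counts, sep = "=", collapse = ", "),
            call. = FALSE)
  }
  attr(tb, "proteins") <- proteins
  tb
}

#' Run the full analysis pipeline on simulated plates
#'
#' End-to-end driver: build the stimulus design, configure the synthetic
#' generator (with a planted discriminative pair), simulate one plate per
#' tissue state, normalize, run PCA + k-means state assignment, fit the
#' OOS-DA projections and the exhaustive pair search, and collect a summary.
#' All randomness derives from `seed`.
#'
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, all tables plus a run log
#'   (seed, package version, stage timings) are written there as delimited
#'   text.
#' @param group_a,group_b Stimulating-protein groups (defaults:
#'   [stimulus_groups()]).
#' @param proteins Measured panel.
#' @param planted_pair,shift Passed to [plant_discriminative_pair()]; set
#'   `planted_pair = NULL` for a null run with exchangeable states.
#' @param state_modulation_sd,heterogeneity_sd,cv Generator parameters (see
#'   [default_generator_config()]).
#' @param pca_dims,k Clustering parameters.
#' @param oosda_r OOS-DA component count.
#' @param n_resamples,fraction Pair-search resampling scheme.
#' @return List of class `cartstate_run` with elements `design`, `config`,
#'   `plates`, `response`, `pca`, `clusters`, `oosda`, `pairs`, `summary`.
#' @export
run_pipeline <- function(seed = 1, out_dir = NULL,
                         group_a = stimulus_groups()$pro_catabolic,
                         group_b = stimulus_groups()$anti_anabolic,
                         proteins = cytokine_panel(),
                         planted_pair = c("MMP9", "IFNG"),
                         shift = c(1.5, -1.5),
                         state_modulation_sd = 0.3,
                         heterogeneity_sd = 0.3,
                         cv = 0.15,
                         pca_dims = 4, k = 2, oosda_r = 2,
                         n_resamples = 100, fraction = 0.8) {
  t0 <- Sys.time()
  design <- build_stimulus_panel(group_a, group_b)
  config <- default_generator_config(
    design, proteins = proteins, seed = seed,
    state_modulation_sd = state_modulation_sd,
    heterogeneity_sd = heterogeneity_sd, cv = cv)
  if (!is.null(planted_pair)) {
    config <- plant_discriminative_pair(config, planted_pair, shift)
  }
  plates <- dplyr::bind_rows(
    simulate_plate(config, design, "healthy", plate_id = "P_H",
                   seed = seed + 1L),
    simulate_plate(config, design, "degrading", plate_id = "P_D",
                   seed = seed + 2L))
  response <- build_response_matrix(plates, design)
  pca <- state_pca(response)
  clusters <- cluster_states(pca, n_dims = pca_dims, k = k, seed = seed + 3L)
  oosda <- fit_oosda(response, r = oosda_r)
  pairs <- exhaustive_pair_search(response, n_resamples = n_resamples,
                                  fraction = fraction, seed = seed + 4L)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  summary <- list(
    seed = seed,
    n_stimuli = nrow(design),
    data_points = count_data_points(design, proteins, n_controls = 1),
    explained_variance = pca$explained_variance,
    confusion = clusters$confusion,
    n_misassigned = clusters$n_misassigned,
    top_pairs = head(pairs$ranking, 10),
    best_pair = pairs$best_pair,
    elapsed_s = elapsed)
  out <- structure(list(design = design, config = config, plates = plates,
                        response = response, pca = pca, clusters = clusters,
                        oosda = oosda, pairs = pairs, summary = summary),
                   class = "cartstate_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mfi_table(plates, file.path(out_dir, "plates.csv"))
    write_response_matrix(response, file.path(out_dir, "response.csv"))
    readr::write_csv(pca$scores, file.path(out_dir, "pca_scores.csv"))
    readr::write_csv(tidy(pca), file.path(out_dir, "pca_loadings.csv"))
    readr::write_csv(tibble::tibble(
      component = seq_along(pca$explained_variance),
      fraction = pca$explained_variance),
      file.path(out_dir, "pca_variance.csv"))
    readr::write_csv(tidy(clusters), file.path(out_dir, "confusion.csv"))
    readr::write_csv(tidy(oosda), file.path(out_dir, "oosda_weights.csv"))
    readr::write_csv(pairs$ranking, file.path(out_dir, "pair_ranking.csv"))
    log_lines <- c(
      paste0("cartstate ", as.character(utils::packageVersion("cartstate"))),
      paste0("seed: ", seed),
      paste0("elapsed_s: ", signif(elapsed, 4)),
      paste0("best_pair: ", paste(pairs$best_pair, collapse = ":")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  out
}

#' @export
print.cartstate_run <- function(x, ...) {
  s <- x$summary
  cat("cartstate pipeline run (seed ", s$seed, ")\n", sep = "")
  cat(" stimuli: ", s$n_stimuli, "; data points per state: ",
      s$data_points, "\n", sep = "")
  ev <- round(100 * s$explained_variance[1:min(4,
    length(s$explained_variance))], 1)
  cat(" PC variance (%): ", paste(ev, collapse = ", "), "\n", sep = "")
  cat(" misassigned: ", paste(names(s$n_misassigned), s$n_misassigned,
                              sep = "=", collapse = ", "), "\n", sep = "")
  cat(" best pair: ", paste(s$best_pair, collapse = " / "), "\n", sep = "")
  invisible(x)
}
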