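#' The 26-protein multiplex detection panel
#'
#' Names of the protein releases measured in the explant supernatant by the
#' multiplex bead-array assay, in assay order.
#'
#' @return Character vector of 26 protein names.
#' @export
#' @examples
#' length(cytokine_panel())
cytokine_panel <- function() {
  c("PEDF", "CXCL11", "IL13", "ZG16", "IL4", "GROA", "IFNG", "CYTC",
    "IL8", "IL17F", "IL12A", "TNFa", "IL1a", "TFF3", "ICAM1", "IL10",
    "FST", "S100A6", "CXCL10", "PROK1", "CCL5", "IL20", "TNFSF12",
    "BMP2", "FGF2", "MMP9")
}

#' Default stimulating-protein groups
#'
#' The 13 stimulating proteins split into a pro-inflammatory / catabolic
#' group and an anti-inflammatory / anabolic group. Singletons from both
#' groups plus all cross-group pairs give the 55-member perturbation panel.
#'
#' @return Named list with elements `pro_catabolic` (6 proteins) and
#'   `anti_anabolic` (7 proteins).
#' @export
stimulus_groups <- function() {
  list(
    pro_catabolic = c("IL1a", "IL1b", "TNFa", "IL6", "IL8", "MMP9"),
    anti_anabolic = c("IL4", "IL10", "IL13", "BMP2", "FGF2", "IGF1", "TGFb1")
  )
}

#' Build the combinatorial stimulus panel
#'
#' Enumerates the perturbation set used throughout the pipeline: every
#' single protein from either group, followed by every cross-group pair
#' (one member from each group). Within-group pairs are never formed; with
#' the default 6 + 7 split this yields 13 + 6*7 = 55 stimuli. Ordering is
#' deterministic: group-a singletons in the given order, then group-b
#' singletons, then pairs looping group a outer, group b inner.
#'
#' @param group_a,group_b Character vectors of stimulating protein names;
#'   the groups must be disjoint (either may be empty).
#' @param concentrations Optional named character vector of opaque
#'   concentration tags per stimulating protein; tags are carried along for
#'   bookkeeping and never enter any computation.
#' @return A tibble of class `stimulus_design` with columns `stimulus_id`,
#'   `protein_1`, `protein_2` (`NA` for singletons), `kind`
#'   (`"single"`/`"pair"`) and `concentration`; the groups are attached as
#'   attributes `group_a` and `group_b`.
#' @export
#' @examples
#' g <- stimulus_groups()
#' design <- build_stimulus_panel(g$pro_catabolic, g$anti_anabolic)
#' nrow(design)  # 55
build_stimulus_panel <- function(group_a, group_b, concentrations = NULL) {
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  shared <- intersect(group_a, group_b)
  if (length(shared) > 0) {
    stop("stimulation groups overlap; shared proteins: ",
         paste(shared, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(group_a) || anyDuplicated(group_b)) {
    stop("duplicated protein names within a stimulation group", call. = FALSE)
  }
  tag <- function(p) {
    if (is.null(concentrations)) return(NA_character_)
    unname(concentrations[p])
  }
  singles <- c(group_a, group_b)
  pairs <- expand.grid(b = group_b, a = group_a,
                       stringsAsFactors = FALSE)[, c("a", "b")]
  # expand.grid varies its first factor fastest; with b first and columns
  # reordered we get group-a outer, group-b inner ordering.
  design <- tibble::tibble(
    stimulus_id = c(singles, paste(pairs$a, pairs$b, sep = "+")),
    protein_1 = c(singles, pairs$a),
    protein_2 = c(rep(NA_character_, length(singles)), pairs$b),
    kind = c(rep("single", length(singles)), rep("pair", nrow(pairs)))
  )
  design$concentration <- ifelse(
    is.na(design$protein_2),
    tag(design$protein_1),
    paste(tag(design$protein_1), tag(design$protein_2), sep = ";")
  )
  attr(design, "group_a") <- group_a
  attr(design, "group_b") <- group_b
  class(design) <- c("stimulus_design", class(design))
  design
}

#' Count raw data points of a perturbation block
#'
#' One plate's perturbation block spans (number of stimuli + number of
#' unstimulated controls) x (number of measured proteins) MFI values; the
#' full 55-stimulus design with one control and the 26-protein panel gives
#' 1456 data points per tissue state.
#'
#' @param design A `stimulus_design` (or any data frame with one row per
#'   stimulus).
#' @param panel Character vector of measured protein names.
#' @param n_controls Number of unstimulated control wells counted with the
#'   block (default 1).
#' @return Integer count.
#' @export
count_data_points <- function(design, panel = cytokine_panel(),
                              n_controls = 1) {
  (nrow(design) + n_controls) * length(panel)
}

#' Proteins stimulating a given stimulus id
#'
#' @noRd
stimulus_members <- function(design, stimulus_id) {
  i <- match(stimulus_id, design$stimulus_id)
  if (is.na(i)) {
    stop("unknown stimulus id: ", stimulus_id, call. = FALSE)
  }
  p <- c(design$protein_1[i], design$protein_2[i])
  p[!is.na(p)]
}
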