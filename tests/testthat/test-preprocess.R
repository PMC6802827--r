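make_table <- function(values, stimulus, state = "healthy", plate = "P1",
                       blanks = rbind(c(40, 40, 40), c(60, 60, 60))) {
  proteins <- paste0("pr", seq_len(ncol(values)))
  tb <- tibble::tibble(
    plate_id = plate,
    well_id = c(sprintf("W%02d", seq_along(stimulus)),
                paste0("blank", seq_len(nrow(blanks)))),
    tissue_state = c(rep(state, length(stimulus)), rep("none", nrow(blanks))),
    stimulus_id = c(stimulus, rep("blank", nrow(blanks))))
  tb[proteins] <- as.data.frame(rbind(values, blanks))
  tb
}

test_that("below-blank masking thresholds at the plate blank mean, per protein", {
  vals <- rbind(c(49, 100, 200), c(51, 100, 30), c(500, 100, 49))
  tb <- make_table(vals, c("s1", "s2", "control"))
  out <- mask_below_blank(tb)   # blank mean is 50 everywhere
  expect_true(is.na(out$pr1[1]))
  expect_false(is.na(out$pr1[2]))
  expect_true(is.na(out$pr3[2]))
  expect_true(is.na(out$pr3[3]))       # control wells are filtered too
  expect_false(is.na(out$pr2[1]))      # nothing above threshold is touched
  # blank rows themselves retain their values
  expect_equal(out$pr1[out$stimulus_id == "blank"], c(40, 60))
  # plates without blanks are an error
  expect_error(mask_below_blank(tb[tb$stimulus_id != "blank", ]), "blank")
})

test_that("masking counts equal the number of wells forced below background", {
  cfg <- tiny_config(cv = 0.1)
  plate <- simulate_plate(cfg, tiny_design(), "healthy", seed = 42)
  forced <- c(2, 5, 9)
  plate$Z[forced] <- 1  # far below the blank mean
  out <- mask_below_blank(plate)
  expect_equal(which(is.na(out$Z)), forced)
})

test_that("self-channel masking hits both members of pair stimuli and spares controls", {
  cfg <- tiny_config(cv = 0)
  d <- tiny_design()
  plate <- simulate_plate(cfg, d, "healthy", seed = 1)
  out <- mask_saturated_self_channels(plate, d)
  expect_true(is.na(out$A1[out$stimulus_id == "A1"]))
  expect_true(is.na(out$A1[out$stimulus_id == "A1+B1"]))
  expect_true(is.na(out$B1[out$stimulus_id == "A1+B1"]))
  expect_false(is.na(out$B1[out$stimulus_id == "A1"]))
  ctrl <- out[out$stimulus_id == "control", ]
  expect_false(anyNA(ctrl[, cfg$proteins]))
  # A2/B2/B3 are not measured, so their wells lose nothing
  expect_false(anyNA(out[out$stimulus_id == "A2", cfg$proteins]))
  bad <- plate
  bad$stimulus_id[1] <- "mystery"
  expect_error(mask_saturated_self_channels(bad, d), "mystery")
})

test_that("nearest-neighbour imputation follows the stated distance and tie rules", {
  m <- rbind(c(1, 2, NA), c(1, 2, 7), c(9, 9, 0))
  expect_equal(impute_missing(m, k = 1)[1, 3], 7)
  # k = 2 averages the two nearest rows observing the column
  m2 <- rbind(c(0, 0, NA), c(0, 0, 4), c(0, 0.0001, 6), c(50, 50, 100))
  expect_equal(impute_missing(m2, k = 2)[1, 3], 5)
  # identity on complete matrices
  full <- matrix(rnorm(12), 4, 3)
  out <- impute_missing(full)
  expect_equal(unclass(out)[, ], full, ignore_attr = TRUE)
  expect_false(any(attr(out, "imputed")))
  # a column missing everywhere cannot be imputed
  m3 <- rbind(c(1, NA), c(2, NA))
  expect_error(impute_missing(m3), "column")
})

test_that("imputation equals the all-pairs brute-force oracle on random matrices", {
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(rnorm(80), 10, 8)
    m[sample(80, 16)] <- NA
    # guard the preconditions of both implementations
    if (any(rowSums(!is.na(m)) == 0) || any(colSums(!is.na(m)) == 0)) next
    for (k in c(1, 3)) {
      expect_equal(unclass(impute_missing(m, k = k))[, ], oracle_impute(m, k),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("the normalized difference honours its bounds, zeros and limits", {
  expect_equal(normalize_difference(5, 5), 0)
  expect_equal(normalize_difference(3, 1), 0.5)
  expect_lt(abs(normalize_difference(1e6, 1) - 1), 1e-5)
  expect_lt(abs(normalize_difference(1, 1e6) + 1), 1e-5)
  # antisymmetry and monotonicity over random positive pairs
  set.seed(2)
  a <- rexp(200) + 1e-6
  b <- rexp(200) + 1e-6
  expect_equal(normalize_difference(a, b), -normalize_difference(b, a))
  f <- sort(runif(50, 0.1, 10))
  expect_true(all(diff(normalize_difference(f, 2)) > 0))
  expect_error(normalize_difference(0, 0), "undefined")
  expect_error(normalize_difference(-1, 2), "non-negative")
})

test_that("response matrices are zero for unperturbed noise-free plates", {
  cfg <- tiny_config(cv = 0)
  d <- tiny_design()
  plate <- simulate_plate(cfg, d, "healthy", seed = 1)
  resp <- build_response_matrix(plate, d)
  expect_equal(nrow(resp), 11)
  expect_equal(resp$stimulus_id, d$stimulus_id)
  vals <- as.matrix(resp[, cfg$proteins])
  expect_equal(max(abs(vals)), 0)
  # self-channels were masked and imputed, and the mask records them
  imp <- attr(resp, "imputed")
  expect_true(imp[which(resp$stimulus_id == "A1"),
                  which(cfg$proteins == "A1")])
})

test_that("a planted threefold response appears as exactly 0.5 after normalization", {
  eff <- tibble::tibble(tissue_state = "*", stimulus_id = "B3",
                        protein = "X", factor = 3)
  cfg <- tiny_config(cv = 0, effects = eff)
  d <- tiny_design()
  resp <- build_response_matrix(simulate_plate(cfg, d, "healthy", seed = 1), d)
  expect_equal(resp$X[resp$stimulus_id == "B3"], 0.5)
  other <- as.matrix(resp[resp$stimulus_id != "B3", c("X", "Y", "Z")])
  expect_equal(max(abs(other)), 0)
})

test_that("full-design plates yield a 55 x 26 response matrix within [-1, 1]", {
  g <- stimulus_groups()
  d <- build_stimulus_panel(g$pro_catabolic, g$anti_anabolic)
  cfg <- default_generator_config(d, seed = 3)
  plate <- simulate_plate(cfg, d, "healthy", seed = 3)
  expect_equal(count_data_points(d, cytokine_panel(), 1), 1456)
  resp <- build_response_matrix(plate, d)
  expect_equal(dim(as.matrix(resp[, cytokine_panel()])), c(55, 26))
  expect_true(all(abs(as.matrix(resp[, cytokine_panel()])) <= 1))
  expect_error(build_response_matrix(
    plate[plate$stimulus_id != "control", ], d), "control")
})

test_that("masking is idempotent on complete above-background tables", {
  cfg <- tiny_config(cv = 0.1)
  plate <- simulate_plate(cfg, tiny_design(), "healthy", seed = 9)
  once <- mask_below_blank(plate)
  expect_equal(mask_below_blank(once), once)
})

test_that("assay CV reports replicate precision and flags imprecise proteins", {
  v1 <- rbind(c(90, 100, 10), c(80, 200, 20), c(100, 150, 30))
  v2 <- rbind(c(110, 100, 30), c(80, 200, 40), c(100, 150, 50))
  t1 <- make_table(v1, c("s1", "s2", "control"))
  t2 <- make_table(v2, c("s1", "s2", "control"))
  qc <- assay_cv(list(t1, t2))
  # pr1: replicate cv is sd/mean = 0.1414 for s1 and 0 for the other two
  # conditions, so the per-protein mean is 0.1414/3
  expect_equal(qc$cv[qc$protein == "pr1"], sd(c(90, 110)) / 100 / 3,
               tolerance = 1e-12)
  expect_equal(qc$cv[qc$protein == "pr2"], 0)
  # pr3 is imprecise at every condition and crosses the 25% flag threshold
  expect_true(qc$flagged[qc$protein == "pr3"])
  expect_false(qc$flagged[qc$protein == "pr2"])
  expect_error(assay_cv(list(t1)), "two")
})

test_that("replicate CV estimates recover the generator noise level", {
  # panel disjoint from the stimulating proteins: railed self-channels have
  # no replicate variance and would dilute the noise estimate
  cfg <- generator_config(proteins = paste0("pr", 1:5),
                          baseline_median = c(1000, 2000, 500, 4000, 800),
                          cv = 0.15)
  d <- tiny_design()
  reps <- lapply(1:50, function(i) {
    simulate_plate(cfg, d, "healthy", plate_id = "P1", seed = 2000 + i)
  })
  qc <- assay_cv(reps)
  expect_true(all(qc$cv > 0.10 & qc$cv < 0.20))
})
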