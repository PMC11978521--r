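# A slide with a smooth proportion field, used across the block.
field_scenario <- function(seed = 23, S = 100, Tn = 3) {
  truth <- generate_truth_pattern(S, Tn, "gaussian-bumps", seed = seed)
  list(truth = truth, g = truth$geometry, P = truth$P_expected)
}

test_that("GP field reproduces constants and interpolates at zero noise", {
  sn <- field_scenario()
  Pconst <- matrix(c(0.3, 0.5, 0.2), nrow(sn$P), 3, byrow = TRUE,
                   dimnames = dimnames(sn$P))
  f <- fit_proportion_field(sn$g, Pconst, pipeline_config())
  q <- predict_proportions(f, rbind(colMeans(sn$g$centers),
                                    sn$g$centers[5, ]))
  expect_equal(unname(q), matrix(c(0.3, 0.5, 0.2), 2, 3, byrow = TRUE),
               tolerance = 1e-3)
  # noise -> 0 limit: training points reproduced
  f0 <- fit_proportion_field(sn$g, sn$P,
                             pipeline_config(gp_noise = 0,
                                             gp_length_scale = 100))
  pred <- predict_proportions(f0, sn$g$centers)
  expect_lt(max(abs(pred - sn$P)), 1e-6)
  expect_error(fit_proportion_field(sn$g, sn$P[1:5, ], pipeline_config()),
               "at least 10")
  gd <- spot_geometry(sprintf("s%d", 1:12), matrix(1, 12, 2), 10)
  expect_error(fit_proportion_field(gd, matrix(1 / 3, 12, 3,
                                               dimnames = list(gd$spot_ids,
                                                               NULL)),
                                    pipeline_config()),
               "degenerate")
})

test_that("held-out prediction beats the global-mean baseline", {
  sn <- field_scenario(seed = 23)
  set.seed(23)
  idx <- sample(nrow(sn$P), 20)
  gtr <- spot_geometry(sn$g$spot_ids[-idx], sn$g$centers[-idx, ],
                       sn$g$spot_diameter_px, sn$g$microns_per_px)
  f <- fit_proportion_field(gtr, sn$P[-idx, , drop = FALSE],
                            pipeline_config(gp_noise = 0.01))
  pred <- predict_proportions(f, sn$g$centers[idx, ])
  mae_gp <- mean(abs(pred - sn$P[idx, ]))
  mae_mean <- mean(abs(matrix(colMeans(sn$P[-idx, ]), length(idx), 3,
                              byrow = TRUE) - sn$P[idx, ]))
  expect_lt(mae_gp, mae_mean)
})

test_that("predictions are simplexes everywhere, far field -> slide average", {
  sn <- field_scenario(seed = 29)
  f <- fit_proportion_field(sn$g, sn$P, pipeline_config())
  set.seed(29)
  coords <- cbind(runif(1000, 0, max(sn$g$centers[, "x"])),
                  runif(1000, 0, max(sn$g$centers[, "y"])))
  pred <- predict_proportions(f, coords)
  expect_true(all(abs(rowSums(pred) - 1) < 1e-9))
  expect_true(all(pred >= 0))
  far <- predict_proportions(f, cbind(1e7, 1e7))
  expect_equal(unname(far[1, ]), unname(f$slide_average),
               tolerance = 1e-6)
  expect_error(predict_proportions(f, cbind(NA, 1)), "finite")
})

test_that("point-geometry (zero-radius) slides fit and predict unchanged", {
  sn <- field_scenario(seed = 31)
  gpt <- spot_geometry(sn$g$spot_ids, sn$g$centers,
                       spot_diameter_px = 1e-9,
                       microns_per_px = sn$g$microns_per_px)
  f <- fit_proportion_field(gpt, sn$P, pipeline_config())
  pred <- predict_proportions(f, sn$g$centers[1:5, ])
  expect_true(all(abs(rowSums(pred) - 1) < 1e-9))
})

test_that("out-spot typing samples the predicted field categorically", {
  sn <- field_scenario(seed = 7)
  f <- fit_proportion_field(sn$g, sn$P, pipeline_config())
  nuc <- nucleus_set(c("a", "b"), rbind(c(100, 100), c(200, 200)))
  t1 <- annotate_out_spot_nuclei(nuc, f, seed = 5)
  t2 <- annotate_out_spot_nuclei(nuc, f, seed = 5)
  expect_identical(t1$assigned_type, t2$assigned_type)
  expect_true(all(t1$assigned_type %in% f$type_ids))
  # one-hot field -> deterministic assignment
  Ponehot <- matrix(rep(c(1, 0, 0), each = nrow(sn$P)), nrow(sn$P),
                    dimnames = dimnames(sn$P))
  fh <- fit_proportion_field(sn$g, Ponehot, pipeline_config())
  th <- annotate_out_spot_nuclei(nuc, fh, seed = 9)
  expect_true(all(th$assigned_type == f$type_ids[1]))
  # a 50/50 prediction draws type 1 about half the time
  Phalf <- matrix(rep(c(0.5, 0.5, 0), each = nrow(sn$P)), nrow(sn$P),
                  dimnames = dimnames(sn$P))
  f5 <- fit_proportion_field(sn$g, Phalf, pipeline_config())
  one <- nucleus_set("z", cbind(mean(sn$g$centers[, "x"]),
                                mean(sn$g$centers[, "y"])))
  draws <- vapply(1:2000, function(sd)
    annotate_out_spot_nuclei(one, f5, seed = sd)$assigned_type,
    character(1))
  expect_lt(abs(mean(draws == f5$type_ids[1]) - 0.5), 0.03)
})

test_that("expression imputation smooths expected per-cell profiles", {
  g <- hex <- generate_truth_pattern(16, 2, "uniform", seed = 1)$geometry
  G <- 6
  types <- c("t1", "t2")
  n_st <- matrix(2L, 16, 2, dimnames = list(g$spot_ids, types))
  # identical type-1 profile everywhere -> imputed profile equals it
  v <- c(4, 2, 0, 1, 3, 0)
  dec <- lapply(g$spot_ids, function(s) {
    U <- rbind(t1 = 2 * v, t2 = rep(1, G))
    colnames(U) <- sprintf("g%d", 1:G)
    list(U = U)
  })
  names(dec) <- g$spot_ids
  got <- impute_cell_expression(c(10, 10), "t1", dec, n_st, g,
                                bandwidth_px = 100, k = 10)
  expect_equal(got, v, tolerance = 1e-9)
  # tiny bandwidth at a spot center -> that spot's per-cell profile
  dec2 <- dec
  dec2[[3]]$U["t1", ] <- 2 * (v + 7)
  got2 <- impute_cell_expression(g$centers[3, ], "t1", dec2, n_st, g,
                                 bandwidth_px = 1e-3, k = 10)
  expect_equal(got2, v + 7, tolerance = 1e-9)
  expect_error(impute_cell_expression(c(0, 0), "zzz", dec, n_st, g, 10),
               "unknown type")
  n0 <- n_st; n0[, "t2"] <- 0L
  expect_error(impute_cell_expression(c(0, 0), "t2", dec, n0, g, 10),
               "absent from every")

  # planted linear gradient recovered at the midpoint
  xs <- g$centers[, "x"]
  grad <- (xs - min(xs)) / (max(xs) - min(xs))   # 0..1 across the slide
  dec3 <- lapply(seq_along(g$spot_ids), function(i) {
    U <- rbind(t1 = 2 * (10 + 20 * grad[i]) * rep(1, G),
               t2 = rep(1, G))
    colnames(U) <- sprintf("g%d", 1:G)
    list(U = U)
  })
  names(dec3) <- g$spot_ids
  mid <- cbind(mean(range(xs)), mean(range(g$centers[, "y"])))
  got3 <- impute_cell_expression(as.vector(mid), "t1", dec3, n_st, g,
                                 bandwidth_px = 150, k = 16)
  expect_lt(median(abs(got3 - 20) / 20), 0.1)
})

test_that("export_pseudo_image writes a round-trippable nucleus table", {
  nuc <- nucleus_set(sprintf("n%d", 1:10), cbind(1:10, 1:10),
                     assigned_spot = c(rep("s1", 6), rep(NA, 4)),
                     assigned_type = rep(c("a", "b"), 5))
  path <- withr::local_tempfile(fileext = ".csv")
  export_pseudo_image(nuc, path)
  back <- read_nuclei(path)
  expect_equal(nrow(back), 10)
  expect_equal(back$assigned_type, nuc$assigned_type)
  bad <- nuc; bad$assigned_type[1] <- NA
  expect_error(export_pseudo_image(bad, path), "untyped")
  png_path <- withr::local_tempfile(fileext = ".png")
  expect_error(export_pseudo_image(nuc, path, palette = c(a = "red"),
                                   out_png = png_path),
               "palette missing")
})
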