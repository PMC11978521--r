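# Exhaustive L1-optimal apportionment over integer compositions.
brute_apportion_objective <- function(p, N) {
  T_ <- length(p)
  grid <- as.matrix(expand.grid(rep(list(0:N), T_)))
  grid <- grid[rowSums(grid) == N, , drop = FALSE]
  min(rowSums(abs(grid / N - matrix(p, nrow(grid), T_, byrow = TRUE))))
}

test_that("apportion_cells solves the printed L1 problem", {
  expect_equal(apportion_cells(c(0.5, 0.3, 0.2), 10), c(5L, 3L, 2L))
  expect_equal(apportion_cells(c(1, 0, 0), 7), c(7L, 0L, 0L))
  # tied optimum: both [6,4] and [5,5] score 0.10; remainder rule picks 6,4
  expect_equal(apportion_cells(c(0.55, 0.45), 10), c(6L, 4L))
  expect_equal(sum(abs(c(6, 4) / 10 - c(0.55, 0.45))),
               brute_apportion_objective(c(0.55, 0.45), 10))
  expect_equal(apportion_cells(c(0.4, 0.6), 0), c(0L, 0L))
  expect_error(apportion_cells(c(0.5, 0.5), -1), "negative")
  expect_error(apportion_cells(c(0.5, 0.4), 5), "simplex")
})

test_that("apportion_cells matches exhaustive search on random instances", {
  set.seed(0)
  for (T_ in 2:4) {
    for (rep in 1:40) {
      p <- as.vector(random_simplex(1, T_))
      for (N in c(1, 3, 7, 12)) {
        n <- apportion_cells(p, N)
        expect_equal(sum(n), N)
        expect_equal(sum(abs(n / N - p)),
                     brute_apportion_objective(p, N),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("threshold_proportions zeroes weak types and renormalizes", {
  expect_equal(threshold_proportions(c(0.6, 0.3, 0.1), 0.15),
               c(2 / 3, 1 / 3, 0))
  p <- c(0.2, 0.5, 0.3)
  expect_equal(threshold_proportions(p, 0), p)
  expect_equal(threshold_proportions(c(0.05, 0.95), 0.1), c(0, 1))
  # nothing survives: argmax kept
  expect_message(out <- threshold_proportions(c(0.4, 0.35, 0.25), 0.5),
                 "argmax")
  expect_equal(out, c(1, 0, 0))
  expect_error(threshold_proportions(c(1, 0), 1), "l_p")
})

test_that("decompose_spot splits counts by the signature-weighted rule", {
  phi <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  rownames(phi) <- c("t1", "t2"); colnames(phi) <- c("gA", "gB")
  sig <- structure(list(phi = phi, type_ids = rownames(phi),
                        gene_ids = colnames(phi), nu = c(1, 1)),
                   class = "signature_matrix")
  # one-hot proportions: everything to the present type
  d <- decompose_spot(c(10, 4), c(1, 0), sig)
  expect_equal(unname(d$U["t1", ]), c(10, 4))
  expect_equal(unname(d$U["t2", ]), c(0, 0))
  # equal proportions, phi column (0.8, 0.2): 10 splits as 8 / 2
  d2 <- decompose_spot(c(10, 0), c(0.5, 0.5), sig)
  expect_equal(unname(d2$U[, "gA"]), c(8, 2))
  # conservation is exact for every gene
  set.seed(19)
  phi3 <- random_simplex(4, 50)
  sig3 <- structure(list(phi = phi3, type_ids = sprintf("t%d", 1:4),
                         gene_ids = sprintf("g%d", 1:50),
                         nu = rep(1, 4)), class = "signature_matrix")
  x <- rpois(50, 20)
  p <- as.vector(random_simplex(1, 4))
  d3 <- decompose_spot(x, p, sig3)
  expect_identical(colSums(d3$U), as.numeric(x))
  # scale equivariance
  d4 <- decompose_spot(2 * x, p, sig3)
  expect_equal(d4$U, 2 * d3$U, tolerance = 1e-12)
  # zero-signature gene falls back to proportions
  phi0 <- rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0))
  sig0 <- structure(list(phi = phi0, type_ids = c("a", "b"),
                         gene_ids = c("g1", "g2", "g3"), nu = c(1, 1)),
                    class = "signature_matrix")
  expect_message(d5 <- decompose_spot(c(2, 2, 10), c(0.25, 0.75), sig0),
                 "zero signature")
  expect_equal(unname(d5$U[, 3]), c(2.5, 7.5))
})

test_that("partition_to_cells conserves type totals in both modes", {
  U <- rbind(t1 = c(8, 2), t2 = c(0, 0))
  colnames(U) <- c("gA", "gB")
  one <- partition_to_cells(U, c(1L, 0L))
  expect_equal(unname(one[1, ]), c(8, 2))
  four <- partition_to_cells(rbind(t1 = c(8, 0)), 4L)
  expect_equal(unname(four), matrix(c(2, 2, 2, 2, 0, 0, 0, 0), 4),
               ignore_attr = "type")
  expect_error(partition_to_cells(rbind(t1 = c(8, 2), t2 = c(0, 6)),
                                  c(1L, 0L)), "zero cells")
  # sampled mode: cell sums reproduce the integerized type counts and the
  # column (gene) totals exactly
  set.seed(21)
  U2 <- matrix(rpois(5 * 20, 6) + runif(100), 5, 20,
               dimnames = list(sprintf("t%d", 1:5), sprintf("g%d", 1:20)))
  x <- round(colSums(U2))
  U2 <- sweep(U2, 2, x / colSums(U2), "*")   # integer column totals
  n <- c(2L, 1L, 3L, 2L, 1L)
  prof <- partition_to_cells(U2, n, mode = "sampled", seed = 21)
  expect_equal(unname(colSums(prof)), as.numeric(x))
  expect_equal(attr(prof, "type"), rep(rownames(U2), n))
  # expected mode sums back to U rows exactly
  prof_e <- partition_to_cells(U2, n, mode = "expected")
  expect_equal(unname(rowsum(prof_e, attr(prof_e, "type"))[rownames(U2), ]),
               unname(U2), tolerance = 1e-12)
})

test_that("annotate_in_spot_nuclei labels exact counts, uniformly at random", {
  nuc <- nucleus_set(sprintf("n%d", 1:3), cbind(1:3, 1:3),
                     assigned_spot = "s1")
  n_st <- matrix(c(2L, 1L, 0L), 1, 3,
                 dimnames = list("s1", c("a", "b", "c")))
  out <- annotate_in_spot_nuclei(nuc, n_st, seed = 3)
  expect_equal(sum(out$assigned_type == "a"), 2)
  expect_equal(sum(out$assigned_type == "b"), 1)
  out2 <- annotate_in_spot_nuclei(nuc, n_st, seed = 3)
  expect_identical(out$assigned_type, out2$assigned_type)
  expect_error(annotate_in_spot_nuclei(nuc[1:2, ], n_st), "nuclei")

  # over seeded replicates each nucleus is type-1 about half the time
  nuc4 <- nucleus_set(sprintf("n%d", 1:4), cbind(1:4, 1:4),
                      assigned_spot = "s1")
  n4 <- matrix(c(2L, 2L), 1, 2, dimnames = list("s1", c("a", "b")))
  freq <- rowMeans(vapply(1:500, function(sd)
    annotate_in_spot_nuclei(nuc4, n4, seed = sd)$assigned_type == "a",
    logical(4)))
  expect_true(all(abs(freq - 0.5) <= 0.05))
})

test_that("decompose_all + build_cell_profiles reproduce the input matrix", {
  sc <- make_scrna(T_types = 3, cells_per_type = 15, G = 80,
                   markers_per_type = 10, seed = 23)
  ref <- make_reference(sc)
  truth <- generate_truth_pattern(12, 3, "uniform", seed = 23)
  sim <- simulate_spots(sc, truth, "none", seed = 23)
  P_tilde <- truth$n_st / rowSums(truth$n_st)
  dec <- decompose_all(sim$X_sim, P_tilde, ref$sig_full)
  # exact conservation per spot and gene
  for (s in seq_along(dec))
    expect_identical(unname(colSums(dec[[s]]$U)),
                     as.numeric(sim$X_sim$matrix[s, ]))
  asg <- assign_nuclei_to_spots(truth$nuclei, truth$geometry)
  nuc <- annotate_in_spot_nuclei(asg$nuclei, truth$n_st, seed = 23)
  cells <- build_cell_profiles(dec, nuc, truth$n_st, mode = "expected")
  merged <- merge_iscrna_to_pseudo_spots(cells,
                                         spot_ids = rownames(truth$n_st))
  expect_equal(unname(merged$matrix), unname(sim$X_sim$matrix),
               tolerance = 1e-12)
})
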