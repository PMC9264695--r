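test_that("dropping undiscriminable pairs removes exactly the below-h pairs", {
  clone <- rbind(m1 = c(0L, 0L, 2L), m2 = c(1L, 0L, 0L))
  P <- suppressMessages(build_pair_power(make_panel(clone), 8))
  dp <- drop_infeasible_pairs(P, 8)
  expect_equal(nrow(dp$dropped), 1L)      # the near-clone pair (total power 1)
  expect_identical(dp$dropped$id_i, "I01")
  expect_true(all(dp$tensor$total >= 8 - 1e-9))
  # no infeasible pairs -> identity
  inst <- random_instance(7, n = 4, m = 10, h = 1)
  dp2 <- drop_infeasible_pairs(inst$P, 1)
  expect_equal(nrow(dp2$dropped), 0L)
  expect_identical(dp2$tensor$P, inst$P$P)
})

test_that("a pair reachable only through shared-heterozygous loci survives dropping when 'm/h' >= h", {
  # 70 shared-het loci at h=8: total 70/8 = 8.75 >= 8 -> kept
  d <- matrix(1L, nrow = 70L, ncol = 2L)
  d[1, 2] <- 1L
  P <- build_pair_power(make_panel(d), 8)
  expect_equal(P$total[1], 70 / 8)
  expect_equal(nrow(drop_infeasible_pairs(P, 8)$dropped), 0L)
})

test_that("minimum-count solves trivial covering instances exactly", {
  # one marker worth h to the single pair -> f* = 1
  P1 <- build_pair_power(make_panel(rbind(m1 = c(0L, 2L), m2 = c(0L, 1L))), 4)
  r1 <- solve_min_count(P1, 4)
  expect_equal(r1$status, "optimal")
  expect_equal(r1$objective, 1)
  expect_identical(r1$solution$selected, "m1")

  # every marker gives p = 1 to the pair; h = 2 -> f* = 2
  d <- matrix(0L, 5, 2)
  d[, 2] <- 1L
  rownames(d) <- paste0("m", 1:5)
  r2 <- solve_min_count(build_pair_power(make_panel(d), 2), 2)
  expect_equal(r2$objective, 2)
  expect_true(check_feasible(r2$solution$selected,
                             build_pair_power(make_panel(d), 2), 2)$feasible)

  # infeasible pair present -> infeasible status with a certificate
  clone <- rbind(m1 = c(0L, 0L), m2 = c(2L, 2L))
  Pc <- suppressMessages(build_pair_power(make_panel(clone), 8))
  rc <- solve_min_count(Pc, 8)
  expect_equal(rc$status, "infeasible")
  expect_equal(nrow(rc$certificate), 1L)
})

test_that("branch-and-bound matches exhaustive enumeration on random instances", {
  found <- 0L
  seed <- 400L
  hs <- c(1, 2, 4)
  while (found < 12L) {
    seed <- seed + 1L
    h <- hs[found %% 3L + 1L]
    inst <- random_instance(seed, n = 3L + found %% 4L, m = 9L + found %% 6L,
                            h = h)
    if (is.null(inst)) next
    found <- found + 1L
    bf <- brute_force_optimum(inst$P$P, h, inst$Q$q)
    rc <- solve_min_count(inst$P, h)
    expect_equal(rc$status, "optimal")
    expect_equal(rc$objective, bf$min_f, info = paste("seed", seed))
    ra <- solve_min_adjacency(inst$P, inst$Q, h)
    expect_equal(ra$status, "optimal")
    expect_equal(ra$objective, bf$min_g, tolerance = 1e-9,
                 info = paste("seed", seed))
    expect_true(check_feasible(ra$solution$selected, inst$P, h)$feasible)
  }
})

test_that("minimum-adjacency prefers isolated markers over clustered equivalents", {
  # four markers, all interchangeable for the single pair; three clustered
  # on one chromosome, one isolated: the optimum must pick the cheapest pair
  d <- matrix(0L, 4, 2)
  d[, 2] <- 1L
  rownames(d) <- paste0("m", 1:4)
  P <- build_pair_power(make_panel(d), 2)   # needs two markers (each p = 1)
  map <- toy_map(paste0("m", 1:4),
                 chrom = c("c1", "c1", "c1", "c2"),
                 pos = c(1e6, 2e6, 3e6, 1e6),
                 chrom_lengths = c(c1 = 40e6, c2 = 40e6))
  Q <- build_adjacency(map, paste0("m", 1:4))
  ra <- solve_min_adjacency(P, Q, 2)
  expect_equal(ra$status, "optimal")
  expect_true("m4" %in% ra$solution$selected)  # isolated marker chosen
  expect_equal(ra$objective, 1)                # one cross-chromosome pair
  bf <- brute_force_optimum(P$P, 2, Q$q)
  expect_equal(ra$objective, bf$min_g)
})

test_that("with uniform cross-chromosome weights, min-g equals C(f*, 2)", {
  found <- FALSE
  seed <- 600L
  while (!found) {
    seed <- seed + 1L
    inst <- random_instance(seed, n = 4, m = 10, h = 2, n_chrom = 10L)
    if (is.null(inst)) next
    # force every marker onto its own chromosome: all q = 1
    map <- toy_map(inst$P$marker_ids, paste0("u", seq_along(inst$P$marker_ids)),
                   rep(1e6, length(inst$P$marker_ids)),
                   stats::setNames(rep(4e7, length(inst$P$marker_ids)),
                                   paste0("u", seq_along(inst$P$marker_ids))))
    Q1 <- build_adjacency(map, inst$P$marker_ids)
    fstar <- solve_min_count(inst$P, 2)$objective
    ra <- solve_min_adjacency(inst$P, Q1, 2)
    expect_equal(ra$objective, choose(fstar, 2))
    found <- TRUE
  }
})

test_that("the linearized model's dummy variables equal the variable products at the optimum", {
  inst <- random_instance(42, n = 4, m = 10, h = 2)
  model <- build_linearized_model(inst$P, inst$Q, 2)
  expect_equal(model$n_power_rows, nrow(inst$P$P))
  expect_equal(model$n_linking_rows, 3L * nrow(model$y_pairs))
  ra <- solve_min_adjacency(inst$P, inst$Q, 2)
  x <- as.numeric(inst$P$marker_ids %in% ra$solution$selected)
  lin <- snppick:::check_linearization(model, x)
  expect_true(lin$linking_ok)
  expect_equal(lin$y, x[model$y_pairs$k] * x[model$y_pairs$l])
  expect_equal(lin$objective, ra$objective, tolerance = 1e-9)
})

test_that("optimal marker count is non-decreasing in the heterozygosity weight", {
  found <- 0L
  seed <- 700L
  while (found < 4L) {
    seed <- seed + 1L
    inst <- random_instance(seed, n = 4, m = 14, h = 8)
    if (is.null(inst) || any(inst$P$total < 8)) next
    found <- found + 1L
    fs <- vapply(c(1, 2, 4, 8), function(h)
      solve_min_count(inst$P, h)$objective, numeric(1))
    expect_true(all(diff(fs) >= 0), info = paste("seed", seed))
  }
})

test_that("the lexicographic pass keeps g optimal while shrinking the set when possible", {
  inst <- random_instance(52, n = 4, m = 10, h = 2)
  plain <- solve_min_adjacency(inst$P, inst$Q, 2)
  lex <- solve_min_adjacency(inst$P, inst$Q, 2, lexicographic = TRUE)
  expect_equal(lex$objective, plain$objective, tolerance = 1e-9)
  expect_lte(lex$solution$f, plain$solution$f)
  expect_true(check_feasible(lex$solution$selected, inst$P, 2)$feasible)
})
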