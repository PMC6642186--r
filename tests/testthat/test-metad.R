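test_that("hills parsing handles PLUMED headers, counts and units", {
  p <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("#! FIELDS time cv sigma_cv height",
               "4.0 0.50 0.02 0.21"), p)
  h <- read_hills(p, units = "nm")
  expect_equal(nrow(h), 1)
  expect_equal(h$center, 5.0)    # 0.5 nm -> 5 A
  expect_equal(h$sigma, 0.2)
  expect_equal(h$height, 0.21)

  # empty body
  writeLines("#! FIELDS time cv sigma_cv height", p)
  expect_equal(nrow(read_hills(p)), 0)

  # plain header + 2500 hills (10 ns at 4 ps)
  hs <- make_hills_set(c(pose = 0.3), n_replicates = 1, seed = 1,
                       dir = withr::local_tempdir())
  h <- read_hills(hs$paths$pose[1])
  expect_equal(nrow(h), 2500)
  expect_equal(h$time[2] - h$time[1], 4)

  # missing column errors
  writeLines(c("#! FIELDS time cv height", "4.0 0.5 0.21"), p)
  expect_error(read_hills(p), "sigma")
})

test_that("free-energy reconstruction is the negated hill sum, shifted", {
  h <- data.frame(time = 4, center = 0.5, sigma = 0.02, height = 1)
  grid <- seq(0.3, 0.7, length.out = 401)
  prof <- reconstruct_free_energy(h, grid)
  i <- which.min(abs(prof$grid - 0.5))
  expect_equal(prof$F[i], 0, tolerance = 1e-10)       # well bottom
  expect_equal(prof$F[1], 1, tolerance = 1e-10)        # far field = +height
  expect_equal(min(prof$F), 0)

  # no hills: flat zero
  empty <- data.frame(time = numeric(), center = numeric(),
                      sigma = numeric(), height = numeric())
  flat <- reconstruct_free_energy(empty, seq(0, 1, length.out = 11))
  expect_true(all(flat$F == 0))

  # 100 random hills vs term-by-term summation at probe points
  set.seed(13)
  h <- data.frame(time = seq_len(100), center = runif(100, 0, 2),
                  sigma = runif(100, 0.05, 0.3), height = runif(100, 0, 1))
  grid <- seq(-1, 3, length.out = 101)
  prof <- reconstruct_free_energy(h, grid)
  direct_all <- sapply(grid, function(s)
    -sum(h$height * exp(-(s - h$center)^2 / (2 * h$sigma^2))))
  expect_equal(prof$F, direct_all - min(direct_all), tolerance = 1e-12)

  # grid not covering the hills warns with the clipped fraction
  expect_warning(reconstruct_free_energy(h, seq(0.9, 1.1,
                                                length.out = 21)),
                 "clipped")
})

test_that("the Boltzmann average behaves like the defining integral", {
  # flat profile: exact midpoint
  flat <- fe_profile(seq(0, 1, length.out = 101), rep(0, 101))
  expect_identical(boltzmann_average(flat), 0.5)

  # narrow harmonic well far from the edges: mean at the minimum
  g <- seq(0, 1, length.out = 2001)
  harm <- fe_profile(g, 400 * (g - 0.3)^2, temperature = 300)
  expect_equal(boltzmann_average(harm), 0.3, tolerance = 1e-3)

  # shift invariance to 1e-10
  set.seed(17)
  Fv <- cumsum(rnorm(101, 0, 0.5)); Fv <- Fv - min(Fv)
  p1 <- fe_profile(seq(0, 2, length.out = 101), Fv)
  p2 <- fe_profile(seq(0, 2, length.out = 101), Fv + 123.456)
  expect_equal(boltzmann_average(p1), boltzmann_average(p2),
               tolerance = 1e-10)

  # coarse vs refined quadrature on an asymmetric double well
  dw <- function(s) 8 * (s - 0.25)^2 * (s - 0.75)^2 * 40 + 2 * s
  g101 <- seq(0, 1, length.out = 101)
  g1e5 <- seq(0, 1, length.out = 100001)
  expect_equal(boltzmann_average(fe_profile(g101, dw(g101))),
               boltzmann_average(fe_profile(g1e5, dw(g1e5))),
               tolerance = 1e-3)

  # the average always lies inside the grid range
  for (k in 1:5) {
    Fv <- abs(rnorm(51, 0, 20))
    p <- fe_profile(seq(-2, 2, length.out = 51), Fv)
    s <- boltzmann_average(p)
    expect_gte(s, -2); expect_lte(s, 2)
  }

  # deep wells must not underflow to NaN
  deep <- fe_profile(seq(0, 1, length.out = 101),
                     1e4 * (seq(0, 1, length.out = 101) - 0.4)^2)
  expect_false(is.nan(boltzmann_average(deep)))

  expect_error(fe_profile(0.5, 0), "grid")
})

test_that("pose ranking orders planted wells and is deterministic on ties", {
  hs <- make_hills_set(c(A = 0.1, B = 0.4), n_replicates = 10, seed = 21)
  profs <- lapply(hs$hills, function(reps)
    lapply(reps, reconstruct_free_energy))
  rk <- rank_poses(profs)
  expect_equal(rk$pose[rk$rank == 1], "A")
  expect_equal(rk$pose[rk$rank == 2], "B")
  expect_true(all(rk$sem >= 0))
  # error bars: the planted well centres are recovered within 3 SEM
  expect_lt(abs(rk$mean[rk$pose == "A"] - 0.1),
            3 * rk$sem[rk$pose == "A"] + 1e-3)
  expect_lt(abs(rk$mean[rk$pose == "B"] - 0.4),
            3 * rk$sem[rk$pose == "B"] + 1e-3)

  # identical replicate sets tie; the lexicographic rule breaks it
  tie <- rank_poses(list(b = profs$A, a = profs$A))
  expect_equal(tie$pose[tie$rank == 1], "a")

  # SEM equals sd/sqrt(n) on known values
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10) / 10
  fake <- lapply(vals, function(v)
    fe_profile(seq(v - 0.05, v + 0.05, length.out = 11), rep(0, 11)))
  rk1 <- rank_poses(list(p = fake, q = fake))
  expect_equal(rk1$sem[1], stats::sd(vals) / sqrt(10), tolerance = 1e-10)

  expect_error(rank_poses(list(A = profs$A[1])), "replicates")
})
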