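test_that("kcross matches single-pair closed forms", {
  cells <- data.frame(x = c(50, 53), y = c(50, 54),
                      cell_type = c("A", "B"))
  win <- c(0, 100, 0, 100)
  # one ordered pair at distance 5 in a 100x100 window
  k10 <- kcross(cells, "A", "B", radii = 10, correction = "none",
                window = win)
  expect_equal(k10$est, 10000)
  expect_equal(kcross(cells, "A", "B", radii = 4, correction = "none",
                      window = win)$est, 0)
  # L transform of those values
  expect_equal(lcross(k10)$est, sqrt(10000 / pi))
  expect_equal(lcross(kcross(cells, "A", "B", radii = 4,
                             correction = "none", window = win))$est, 0)
})

test_that("L curve equals r when K is the CSR reference", {
  k <- coloctest:::new_curve(c(10, 20, 30), pi * c(10, 20, 30)^2, "K",
                             "A", "B", 5, 5, "none", c(0, 1, 0, 1))
  expect_equal(lcross(k)$est, c(10, 20, 30))
})

test_that("zero counts give flagged missing estimates, not errors", {
  cells <- data.frame(x = 1:3, y = 1:3,
                      cell_type = c("A", "A", "A"))
  k <- kcross(cells, "A", "B", radii = c(5, 10), window = c(0, 10, 0, 10))
  expect_true(all(is.na(k$est)))
  expect_equal(attr(k, "n_j"), 0)
  # self-pair with a single cell is likewise undefined
  one <- data.frame(x = 1, y = 1, cell_type = "A")
  expect_true(all(is.na(kcross(one, "A", "A", radii = 5,
                               window = c(0, 10, 0, 10))$est)))
  expect_error(kcross(cells, "A", "B", radii = 5,
                      window = c(0, 10, 0, 10), correction = "hex"),
               "correction")
})

test_that("kcross equals the naive double-loop oracle for every correction", {
  win <- c(0, 200, 0, 300)
  radii <- c(10, 25, 60, 110)
  for (seed in 1:6) {
    set.seed(seed)
    n_a <- sample(5:40, 1); n_b <- sample(5:40, 1)
    a <- csr_points(n_a, win); b <- csr_points(n_b, win)
    cells <- data.frame(x = c(a$x, b$x), y = c(a$y, b$y),
                        cell_type = rep(c("A", "B"), c(n_a, n_b)))
    for (corr in c("none", "translation", "isotropic")) {
      got <- kcross(cells, "A", "B", radii = radii, correction = corr,
                    window = win)$est
      want <- oracle_kcross(a$x, a$y, b$x, b$y, radii, win, corr)
      expect_equal(got, want, tolerance = 1e-10)
      # self-pair path (n(n-1) normalizer, self matches excluded)
      got_self <- kcross(cells, "A", "A", radii = radii, correction = corr,
                         window = win)$est
      want_self <- oracle_kcross(a$x, a$y, a$x, a$y, radii, win, corr,
                                 self = TRUE)
      expect_equal(got_self, want_self, tolerance = 1e-10)
    }
  }
})

test_that("K is monotone non-decreasing in r under every correction", {
  win <- c(0, 500, 0, 500)
  radii <- seq(5, 150, by = 5)
  set.seed(42)
  cells <- random_two_type(60, 45, win, seed = 42)
  for (corr in c("none", "translation", "isotropic")) {
    k <- kcross(cells, "A", "B", radii = radii, correction = corr,
                window = win)$est
    expect_true(all(diff(k) >= 0))
    expect_true(all(k >= 0))
  }
})

test_that("unordered pair counts are symmetric without edge correction", {
  win <- c(0, 300, 0, 300)
  cells <- random_two_type(30, 50, win, seed = 7)
  radii <- c(20, 50, 90)
  k_ab <- kcross(cells, "A", "B", radii = radii, correction = "none",
                 window = win)
  k_ba <- kcross(cells, "B", "A", radii = radii, correction = "none",
                 window = win)
  area <- 300 * 300
  expect_equal(30 * 50 * k_ab$est / area, 50 * 30 * k_ba$est / area,
               tolerance = 1e-12)
})

test_that("score identities: null reference, single radius, scaling", {
  win <- c(0, 400, 0, 400)
  cells <- random_two_type(40, 40, win, seed = 11)
  radii <- seq(10, 100, by = 10)

  # u is the summed departure of L from the identity line
  l <- lcross(kcross(cells, "A", "B", radii = radii, window = win))
  u <- coloc_score(cells, "A", "B", radii = radii, window = win)$u
  expect_equal(u, sum(l$est - l$r))

  # single-radius grid reduces to L(r0) - r0
  r0 <- 35
  l0 <- lcross(kcross(cells, "A", "B", radii = r0, window = win))
  expect_equal(coloc_score(cells, "A", "B", radii = r0, window = win)$u,
               l0$est - r0)

  # scale equivariance: scaling coordinates, window and radii by c scales u
  for (cc in c(0.25, 3)) {
    scaled <- cells
    scaled$x <- scaled$x * cc
    scaled$y <- scaled$y * cc
    u_sc <- coloc_score(scaled, "A", "B", radii = radii * cc,
                        window = win * cc)$u
    expect_equal(u_sc, cc * u, tolerance = 1e-10)
  }
})

test_that("mean score over seeded CSR images is centred at zero", {
  # under complete spatial randomness u has expectation ~0; average over
  # replicate images must sit within Monte-Carlo error of 0
  set.seed(303)
  win <- c(0, 1000, 0, 1000)
  u <- replicate(80, {
    cells <- data.frame(x = runif(400, 0, 1000), y = runif(400, 0, 1000),
                        cell_type = rep(c("A", "B"), each = 200))
    coloc_score(cells, "A", "B", window = win)$u
  })
  expect_lt(abs(mean(u)), 3 * sd(u) / sqrt(length(u)))
})

test_that("score_pairs covers ordered pairs and matches single calls", {
  cells <- rbind(
    cbind(random_two_type(8, 5, c(0, 100, 0, 100), seed = 1),
          image_id = "im1"),
    cbind(random_two_type(4, 9, c(0, 100, 0, 100), seed = 2),
          image_id = "im2")
  )
  study <- cell_study(cells, window = c(0, 100, 0, 100))
  s <- score_pairs(study)
  expect_equal(nrow(s), 8) # 2 images x 4 ordered pairs incl. self-pairs
  expect_setequal(paste(s$type_i, s$type_j),
                  c("A A", "A B", "B A", "B B"))
  for (i in seq_len(nrow(s))) {
    single <- coloc_score(cells[cells$image_id == s$image_id[i], ],
                          s$type_i[i], s$type_j[i],
                          window = c(0, 100, 0, 100))
    expect_equal(s$u[i], single$u)
    expect_equal(s$n_i[i], single$n_i)
  }
  expect_error(score_pairs(study, types = c("A", "Q")), "Q")
})
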