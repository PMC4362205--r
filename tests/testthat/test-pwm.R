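# Multinomial PWM construction, background correction, site structure.

test_that("multinomial counts match the hand-counted fixture", {
  reads <- c(rep("ACG", 5), rep("TCG", 2), "AGG")
  m <- multinomial_matrix(reads, "ACG", order = 1, flank = 0)
  want <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), 1:3))
  want["A", 1] <- 5; want["T", 1] <- 2
  want["C", 2] <- 5; want["G", 2] <- 1
  want["G", 3] <- 5
  expect_equal(m, want)
})

test_that("reads equal to the seed fill only the seed cells", {
  reads <- rep("GGATCC", 20)
  m <- multinomial_matrix(reads, "GGATCC")
  expect_equal(sum(m), 20 * 6)
  for (i in 1:6)
    expect_equal(m[substring("GGATCC", i, i), i], 20)
})

test_that("multinomial matrix agrees with the double-loop oracle", {
  reads <- random_reads(150, 12, seed = 23)
  for (order in 1:2) {
    for (flank in 0:1) {
      m <- multinomial_matrix(reads, "ACGTA", order = order, flank = flank,
                              strand_policy = "forward_only")
      want <- r_multinomial(reads, "ACGTA", order = order, flank = flank)
      expect_equal(m, want)
    }
  }
  # gapped seed
  m <- multinomial_matrix(reads, "ACnGT", order = 1, flank = 1,
                          strand_policy = "forward_only")
  expect_equal(m, r_multinomial(reads, "ACnGT", order = 1, flank = 1))
})

test_that("cell counts are non-decreasing in the multinomial order", {
  reads <- random_reads(200, 10, seed = 29)
  m1 <- multinomial_matrix(reads, "GGATC", order = 1)
  m2 <- multinomial_matrix(reads, "GGATC", order = 2)
  m3 <- multinomial_matrix(reads, "GGATC", order = 3)
  expect_true(all(m2 >= m1))
  expect_true(all(m3 >= m2))
})

test_that("strand merging finds reverse-strand windows", {
  m <- multinomial_matrix("CGTT", "AACG", order = 1, flank = 0)
  expect_equal(unname(m["A", 1]), 1)  # via the reverse strand
  expect_equal(sum(m), 4)
})

test_that("background correction anchors: self, uniform, none", {
  obs <- matrix(c(10, 2, 5, 3, 1, 15, 2, 2, 4, 4, 4, 8), 4, 3,
                dimnames = list(c("A", "C", "G", "T"), 1:3))
  # background identical to observed -> exactly uniform columns
  f <- background_correct(obs, background = obs, mode = "cycle0")
  expect_equal(unname(f), matrix(0.25, 4, 3), tolerance = 1e-12)

  # mode none: plain column proportions
  col <- matrix(c(5, 0, 0, 2), 4, 1, dimnames = list(c("A","C","G","T"), 1))
  fn <- background_correct(col, mode = "none")
  expect_equal(unname(fn[, 1]), c(5 / 7, 0, 0, 2 / 7))

  # uniform mode is a no-op after renormalization
  fu <- background_correct(obs, mode = "uniform")
  expect_equal(fu, sweep(obs, 2, colSums(obs), "/"))
  # columns always sum to one
  expect_true(all(abs(colSums(f) - 1) < 1e-9))
})

test_that("planted PWM frequencies are recovered from simulated SELEX", {
  planted <- matrix(c(.70, .10, .10, .10,
                      .05, .80, .10, .05,
                      .10, .10, .70, .10,
                      .10, .15, .60, .15,
                      .05, .05, .05, .85,
                      .60, .20, .10, .10), 4, 6,
                    dimnames = list(c("A", "C", "G", "T"), 1:6))
  model <- ground_truth_model(site_pwm(planted), selection_strength = 5,
                              cycles = 3, reads_per_cycle = 20000,
                              rng_seed = 11)
  sim <- simulate_experiment(model)
  consensus <- paste(rownames(planted)[apply(planted, 2, which.max)],
                     collapse = "")
  pwm <- build_pwm(sim$cycle3, consensus, order = 1, flank = 0,
                   background = sim$cycle0, background_mode = "cycle0")
  cors <- vapply(1:6, function(j)
    cor(pwm$frequencies[, j], planted[, j]), numeric(1))
  expect_true(all(cors >= 0.95))
})

test_that("build_pwm composes the stages and records metadata", {
  reads <- cycle_reads(random_reads(100, 12, seed = 31), cycle = 3)
  pwm <- build_pwm(reads, "ACGTA", order = 1, flank = 2)
  expect_s3_class(pwm, "selex_pwm")
  expect_equal(ncol(pwm$counts), 5 + 2 * 2)      # span + 2*flank
  expect_equal(pwm$cycle_used, 3L)
  expect_equal(pwm$seed, "ACGTA")
  expect_equal(pwm$counts,
               multinomial_matrix(reads, "ACGTA", order = 1, flank = 2))
  expect_true(all(abs(colSums(pwm$frequencies) - 1) < 1e-9))

  # round-trip of the count matrix through the TSV writer
  path <- tempfile(fileext = ".tsv")
  write_pwm(pwm, path)
  expect_equal(unname(read_pwm(path)), unname(pwm$counts))
})

test_that("site-structure classification separates repeat counts", {
  onehot <- function(word) {
    m <- matrix(0.01 / 3, 4, nchar(word),
                dimnames = list(c("A", "C", "G", "T"), 1:nchar(word)))
    s <- strsplit(word, "")[[1]]
    for (i in seq_along(s)) m[s[i], i] <- 0.99
    m
  }
  expect_equal(classify_site_structure(onehot("TAAT")), "monomer")
  dimer <- cbind(onehot("AAGGTCA"), matrix(0.25, 4, 1), onehot("AAGGTCA"))
  rownames(dimer) <- c("A", "C", "G", "T")
  expect_equal(classify_site_structure(dimer), "dimer")
  trimer <- cbind(onehot("AAGGTCA"), onehot("AAGGTCA"), onehot("AAGGTCA"))
  rownames(trimer) <- c("A", "C", "G", "T")
  expect_equal(classify_site_structure(trimer), "trimer")
  dod <- cbind(onehot("AAGGTCA"), onehot("AAGGTCA"),
               onehot("AAGGTCA"), onehot("AAGGTCA"))
  rownames(dod) <- c("A", "C", "G", "T")
  expect_equal(classify_site_structure(dod), "dimer_of_dimers")
})
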