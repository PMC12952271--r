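wt33 <- wt_cdr_default()

test_that("landscape sampling is reproducible and zeroes wild-type entries", {
  spec <- landscape_spec("simple")
  ls1 <- sample_landscape(spec, wt33, seed = 5)
  ls2 <- sample_landscape(spec, wt33, seed = 5)
  expect_identical(ls1$h, ls2$h)
  expect_identical(ls1$J, ls2$J)
  expect_false(identical(ls1$h, sample_landscape(spec, wt33, seed = 6)$h))
  # h_i(wt_i) = 0 and J zeroed on wild-type letters
  expect_true(all(ls1$h[cbind(seq_len(33), match(wt33$chars, aa_alphabet()))] == 0))
  expect_identical(evaluate_landscape(ls1, wt33$sequence), ls1$f_wt)
  expect_error(landscape_spec("custom"), "moments")
})

test_that("landscape evaluation matches single-term and brute-force oracles", {
  ls <- sample_landscape(landscape_spec("hard"), wt33, seed = 7, f_wt = 1.5)
  # single mutant: baseline plus one field term
  s1 <- wt33$chars; s1[4] <- "W"
  expect_equal(evaluate_landscape(ls, paste(s1, collapse = "")),
               1.5 + ls$h[[4, "W"]])
  # identity substitution record scores the baseline
  expect_equal(evaluate_landscape(ls, wt33$sequence), 1.5)
  # random triple mutants against an exhaustive double-loop oracle
  set.seed(8)
  for (rep in 1:10) {
    pos <- sort(sample.int(33, 3))
    ch <- wt33$chars
    for (p in pos) ch[p] <- sample(setdiff(aa_alphabet(), ch[p]), 1)
    val <- 1.5 + sum(vapply(pos, function(p) ls$h[p, ch[p]], numeric(1)))
    for (u in 1:2) for (v in (u + 1):3) {
      i <- pos[u]; j <- pos[v]
      pid <- (i - 1) * 33 - (i * (i - 1)) %/% 2 + (j - i)
      val <- val + ls$J[pid, ch[i], ch[j]]
    }
    expect_equal(evaluate_landscape(ls, paste(ch, collapse = "")), val)
  }
  expect_error(evaluate_landscape(ls, "AAA"), "length")
})

test_that("without couplings the landscape is exactly additive", {
  spec <- landscape_spec("custom", h_mean = -0.5, h_sd = 0.5,
                         j_mean = 0, j_sd = 0)
  ls <- sample_landscape(spec, wt33, seed = 9)
  ch <- wt33$chars
  a <- ch; a[2] <- "W"
  b <- ch; b[10] <- "K"
  d <- ch; d[2] <- "W"; d[10] <- "K"
  expect_equal(evaluate_landscape(ls, paste(d, collapse = "")),
               evaluate_landscape(ls, paste(a, collapse = "")) +
                 evaluate_landscape(ls, paste(b, collapse = "")))
})

test_that("datasets have the right composition, noise level and uniqueness", {
  ls <- sample_landscape(landscape_spec("simple"), wt33, seed = 10)
  ds <- build_dataset(ls, n_double = 150, n_triple = 250, noise_sd = 1,
                      seed = 11)
  expect_identical(nrow(ds), 660L + 150L + 250L)
  expect_identical(sum(ds$n_mutations <= 1), 660L)  # includes 33 identities
  expect_identical(sum(ds$n_mutations == 2), 150L)
  expect_identical(sum(ds$n_mutations == 3), 250L)
  for (k in 2:3)
    expect_false(anyDuplicated(ds$sequence[ds$n_mutations == k]) > 0)
  resid <- ds$observed_faff - ds$true_faff
  expect_lt(abs(stats::sd(resid) - 1), 0.1)
  expect_lt(abs(mean(resid)), 0.15)
  # zero noise reproduces the true values exactly
  ds0 <- build_dataset(ls, n_double = 20, n_triple = 20, noise_sd = 0,
                       seed = 12)
  expect_identical(ds0$observed_faff, ds0$true_faff)
  expect_equal(ds0$true_faff, evaluate_landscape(ls, ds0$sequence))
  # impossible requests are refused
  small_wt <- wildtype("AC")
  ls_small <- sample_landscape(landscape_spec("simple"), small_wt, seed = 1,
                               alphabet = toy_ab3)
  expect_error(build_dataset(ls_small, n_double = 100, n_triple = 0,
                             seed = 1), "exist")
})

test_that("random mutations are more deleterious under the hard model", {
  # expected effect of a random k-mutant decays faster in k for the hard
  # parameterization, because couplings dominate fields
  mean_effect <- function(mode, k, n = 1500) {
    ls <- sample_landscape(landscape_spec(mode), wt33, seed = 20)
    set.seed(21)
    vals <- vapply(seq_len(n), function(i) {
      pos <- sort(sample.int(33, k))
      ch <- wt33$chars
      for (p in pos) ch[p] <- sample(setdiff(aa_alphabet(), ch[p]), 1)
      evaluate_landscape(ls, paste(ch, collapse = ""))
    }, numeric(1))
    mean(vals)
  }
  for (k in 2:3)
    expect_lt(mean_effect("hard", k) - mean_effect("hard", 1),
              mean_effect("simple", k) - mean_effect("simple", 1))
})

test_that("negative examples are uniform with one shared weak affinity", {
  neg <- generate_negatives(wt33, n = 2000, ka = 1e7, seed = 30)
  expect_identical(nrow(neg), 2000L)
  expect_true(all(neg$faff == -2))   # Kd = 1/Ka = 100 nM -> log10(1/100)
  letters1 <- substr(neg$sequence, 1, 1)
  expect_gt(stats::chisq.test(table(factor(letters1,
                                           levels = aa_alphabet())))$p.value,
            0.001)
  expect_identical(generate_negatives(wt33, 5, seed = 1)$sequence,
                   generate_negatives(wt33, 5, seed = 1)$sequence)
})
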