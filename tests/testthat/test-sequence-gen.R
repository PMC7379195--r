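test_that("interdeviant gaps follow the discretized truncated normal", {
  set.seed(42)
  g <- sample_interdeviant_gaps(10000)
  expect_true(all(g >= 3 & g <= 11))
  expect_lt(abs(mean(g) - 7), 0.1)
  # symmetry about the mean
  tab <- table(factor(g, levels = 3:11)) / length(g)
  for (d in 1:4) {
    expect_lt(abs(tab[[as.character(7 - d)]] - tab[[as.character(7 + d)]]),
              0.015)
  }
  # chi-square sanity check against the renormalized normal pmf
  p <- dnorm(3:11, 7, 2); p <- p / sum(p)
  set.seed(7)
  g2 <- sample_interdeviant_gaps(1e5)
  chi <- suppressWarnings(chisq.test(table(factor(g2, levels = 3:11)), p = p))
  expect_gt(chi$p.value, 1e-4)
})

test_that("degenerate gap support collapses to a point", {
  expect_identical(sample_interdeviant_gaps(3, 5, 2, 5, 5), c(5L, 5L, 5L))
})

test_that("invalid gap parameters error", {
  expect_error(sample_interdeviant_gaps(5, 7, -1, 3, 11), "gap_sd")
  expect_error(sample_interdeviant_gaps(5, 7, 2, 11, 3), "gap_min")
  expect_error(seq_spec(gap_sd = 0), "gap_sd")
  expect_error(seq_spec(gap_min = 12, gap_max = 11))
})

test_that("oddball blocks have exact deviant counts and minimum gaps", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    s <- make_oddball_sequence(seq_spec())
    analyzed <- s[!s$is_warmup, ]
    expect_equal(nrow(analyzed), 360)
    expect_equal(sum(analyzed$role == "deviant"), 45)
    expect_true(all(analyzed$frequency_hz[analyzed$role == "deviant"] == 500))
    expect_true(all(analyzed$frequency_hz[analyzed$role == "standard"] == 550))
    # min gap: standards between successive deviants (warm-up counts first)
    dev <- which(analyzed$role == "deviant")
    expect_true(all(diff(dev) - 1 >= 3))
    n_before_first <- dev[1] - 1 + sum(s$is_warmup)
    expect_gte(n_before_first, 3)
  }
})

test_that("oddball generation is deterministic given the seed", {
  set.seed(99); a <- make_oddball_sequence(seq_spec())
  set.seed(99); b <- make_oddball_sequence(seq_spec())
  expect_identical(a, b)
})

test_that("cascade blocks repeat the fixed up-and-down cycle", {
  s <- make_cascade_sequence(seq_spec(n_trials = 16))
  analyzed <- s[!s$is_warmup, ]
  cyc <- c(500, 550, 605, 666, 732, 666, 605, 550)
  expect_equal(analyzed$frequency_hz, rep(cyc, 2))
  # warm-up is one set without the control tone
  expect_equal(s$frequency_hz[s$is_warmup], cyc[-1])

  big <- make_cascade_sequence(seq_spec())
  st <- sequence_stats(big)
  expect_identical(st$n_adjacent_repeats, 0L)
  props <- tibble::deframe(st$proportions[, c("frequency_hz", "prop")])
  expect_equal(props[["500"]], 1 / 8)
  expect_equal(props[["732"]], 1 / 8)
  expect_equal(props[["550"]], 2 / 8)
  expect_equal(props[["605"]], 2 / 8)
  expect_equal(props[["666"]], 2 / 8)
})

test_that("no-repetition blocks never repeat and match the cascade multiset", {
  cyc_multiset <- sort(c(500, 550, 605, 666, 732, 666, 605, 550))
  for (seed in 1:100) {
    set.seed(seed)
    s <- make_norep_sequence(seq_spec())
    f <- s$frequency_hz
    expect_equal(nrow(s), 367)
    expect_identical(sum(f[-1] == f[-length(f)]), 0L)
    analyzed <- s[!s$is_warmup, ]
    sets <- split(analyzed$frequency_hz, analyzed$set_index)
    expect_true(all(vapply(sets, function(x) identical(sort(x), cyc_multiset),
                           logical(1))))
  }
})

test_that("different seeds give different norep orderings, same multisets", {
  set.seed(1); a <- make_norep_sequence(seq_spec())
  set.seed(2); b <- make_norep_sequence(seq_spec())
  expect_false(identical(a$frequency_hz, b$frequency_hz))
  expect_identical(sort(a$frequency_hz), sort(b$frequency_hz))
})

test_that("cascade and norep proportions are identical for any seed", {
  for (seed in c(5, 17)) {
    set.seed(seed)
    pc <- sequence_stats(make_cascade_sequence(seq_spec()))$proportions
    pn <- sequence_stats(make_norep_sequence(seq_spec()))$proportions
    expect_equal(pc, pn)
  }
})

test_that("sequence_stats reports oddball proportions and gap histogram", {
  set.seed(3)
  st <- sequence_stats(make_oddball_sequence(seq_spec()))
  props <- tibble::deframe(st$proportions[, c("frequency_hz", "prop")])
  expect_equal(props[["500"]], 0.125)
  expect_equal(props[["550"]], 0.875)
  expect_true(all(st$gap_histogram$gap >= 3 & st$gap_histogram$gap <= 11))
  expect_equal(sum(st$gap_histogram$n), 44)
})

test_that("a single-event sequence has zero adjacent repeats", {
  s <- make_cascade_sequence(seq_spec(n_trials = 8))[8, ]
  expect_identical(sequence_stats(s)$n_adjacent_repeats, 0L)
})

test_that("sequences round-trip through TSV", {
  set.seed(4)
  s <- make_cascade_sequence(seq_spec(n_trials = 24))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sequence_tsv(s, path)
  back <- read_sequence_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(s),
               ignore_attr = TRUE)
})
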