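cfg <- stabilityConfig()

test_that("early-stop censoring replaces values from the first crossing", {
  t <- seq(0.1, 10, by = 0.1)
  below <- RmsdSeries(t, rep(2, length(t)))
  expect_identical(applyEarlyStop(below, cfg), below)
  expect_true(is.na(censoredFrom(applyEarlyStop(below, cfg))))

  v <- ifelse(t < 4, 2, 6)
  crossed <- applyEarlyStop(RmsdSeries(t, v), cfg)
  expect_equal(censoredFrom(crossed), which(t >= 4)[1])
  expect_true(all(seriesValues(crossed)[t >= 4] == 10))
  expect_true(all(seriesValues(crossed)[t < 4] == 2))

  first <- applyEarlyStop(RmsdSeries(t, rep(6, length(t))), cfg)
  expect_equal(censoredFrom(first), 1L)
  expect_true(all(seriesValues(first) == 10))
})

test_that("a value at exactly the threshold does not trigger censoring", {
  t <- c(1, 2, 3)
  s <- applyEarlyStop(RmsdSeries(t, c(2, 5.5, 2)), cfg)
  expect_true(is.na(censoredFrom(s)))
})

test_that("censoring is idempotent and never lowers a value", {
  set.seed(20)
  for (k in 1:10) {
    tr <- makeTrajectory(if (k %% 2) "stable" else "escaping",
                         crossTime = runif(1, 1, 8), seed = 800 + k)
    for (s in tr$replicates) {
      once <- applyEarlyStop(s, cfg)
      twice <- applyEarlyStop(once, cfg)
      expect_equal(seriesValues(twice), seriesValues(once))
      expect_equal(censoredFrom(twice), censoredFrom(once))
      expect_true(all(seriesValues(once) >= seriesValues(s) - 1e-12))
    }
  }
})

test_that("whole-replicate censoring mode censors from the first frame", {
  t <- c(1, 2, 3, 4)
  s <- RmsdSeries(t, c(2, 6, 2, 2))
  whole <- applyEarlyStop(s, stabilityConfig(wholeReplicate = TRUE))
  expect_equal(censoredFrom(whole), 1L)
  expect_true(all(seriesValues(whole) == 10))
})

test_that("replicate median is pointwise with mean-of-central-pair ties", {
  t <- c(1, 2, 3)
  mk <- function(v) RmsdSeries(t, v)
  same <- medianAcrossReplicates(list(mk(c(1, 2, 3)), mk(c(1, 2, 3)),
                                      mk(c(1, 2, 3))))
  expect_equal(seriesValues(same), c(1, 2, 3))

  med <- medianAcrossReplicates(list(mk(c(1, 1, 1)), mk(c(2, 2, 2)),
                                     mk(c(9, 9, 9))))
  expect_equal(seriesValues(med), c(2, 2, 2))

  even <- medianAcrossReplicates(list(mk(c(1, 1, 1)), mk(c(3, 3, 3))))
  expect_equal(seriesValues(even), c(2, 2, 2))

  expect_error(medianAcrossReplicates(list()), "no replicate")
})

test_that("replicate order never changes the median series", {
  set.seed(21)
  tr <- makeTrajectory("stable", seed = 77)
  reps <- tr$replicates
  for (k in 1:5) {
    perm <- sample(3)
    expect_equal(seriesValues(medianAcrossReplicates(reps[perm])),
                 seriesValues(medianAcrossReplicates(reps)))
  }
})

test_that("differing grids are resampled by nearest time with a warning", {
  a <- RmsdSeries(c(1, 2, 3), c(1, 2, 3))
  b <- RmsdSeries(c(1.04, 2.04, 3.04), c(10, 20, 30))
  expect_warning(m <- medianAcrossReplicates(list(a, b)), "resampling")
  expect_equal(seriesTimes(m), c(1, 2, 3))
  expect_equal(seriesValues(m), c(5.5, 11, 16.5))
})

test_that("window median takes the closed 9-10 ns interval", {
  t <- seq(0.1, 10, by = 0.1)
  const <- RmsdSeries(t, rep(1.54, length(t)))
  expect_equal(windowMedian(const, cfg), 1.54)

  ramp <- RmsdSeries(t, t)  # linear: median of window frames = median frame
  win <- t[t >= 9 & t <= 10]
  expect_equal(windowMedian(ramp, cfg), stats::median(win))

  short <- RmsdSeries(c(1, 2, 3), c(1, 1, 1))
  expect_error(windowMedian(short, cfg), "window")
})

test_that("window median is monotone under pointwise domination", {
  set.seed(22)
  t <- seq(0.1, 10, by = 0.1)
  for (k in 1:10) {
    v <- runif(length(t), 0, 5)
    bump <- v + runif(length(t), 0, 1)
    expect_gte(windowMedian(RmsdSeries(t, bump), cfg),
               windowMedian(RmsdSeries(t, v), cfg))
  }
})

test_that("binding classification is strict at the 5.5 A threshold", {
  expect_true(classifyBinding(1.54, cfg))
  expect_false(classifyBinding(10, cfg))
  expect_false(classifyBinding(5.5, cfg))
  expect_true(classifyBinding(5.499, cfg))
})

test_that("ligand ranking reproduces the published reference table", {
  ref <- mdReferenceMedians()
  ranked <- rankLigands(data.frame(id = ref$name,
                                   windowMedian = ref$median_rmsd))
  expect_equal(ranked$id[1], "Empagliflozin")
  expect_equal(ranked$windowMedian[1], 1.54)
  # the published rank column is reproduced exactly
  expect_equal(ranked$rank[match(ref$name, ranked$id)], ref$rank)
  # eight compounds lie strictly between 1 and 2 Angstrom
  expect_equal(sum(ref$median_rmsd > 1 & ref$median_rmsd < 2), 8)
  single <- rankLigands(data.frame(id = "only", windowMedian = 3))
  expect_equal(single$rank, 1)
})

test_that("full stability pipeline recovers planted labels", {
  stable <- makeTrajectory("stable", mu = 1.5, sigma = 0.2, seed = 7)
  rs <- compoundStability("stable", stable$replicates)
  expect_true(rs$bound)
  expect_lt(rs$windowMedian, 5.5)

  esc <- makeTrajectory("escaping", crossTime = 4, seed = 7)
  re <- compoundStability("esc", esc$replicates)
  expect_false(re$bound)
  # crossing before the window start censors the whole window
  expect_equal(re$windowMedian, 10)
  expect_equal(re$nCensored, 3)
})

test_that("a wrong replicate count warns but still computes", {
  tr <- makeTrajectory("stable", seed = 30)
  expect_warning(r <- compoundStability("x", tr$replicates[1:2]),
                 "2 replicates")
  expect_true(r$bound)
})
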