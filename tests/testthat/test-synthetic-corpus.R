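test_that("a jitter-free regular train places beats on the exact grid", {
  set.seed(1)
  rec <- render_beat_train(data.frame(class = "NSR", duration_s = 10),
                           gp_regular(60), fs = 250)
  expect_equal(rec$beats$sample, seq(0, 2250, by = 250))
  expect_true(all(rec$beats$class == "NORMAL"))
  expect_equal(rec$rhythms, data.frame(start = 0, end = 2500, class = "NSR"))
})

test_that("noise episodes carry no beats and one NOISE interval", {
  set.seed(1)
  rec <- render_beat_train(data.frame(class = "NOISE", duration_s = 5),
                           gen_params(), fs = 250)
  expect_equal(nrow(rec$beats), 0)
  expect_equal(rec$rhythms, data.frame(start = 0, end = 1250, class = "NOISE"))
})

test_that("AFib episodes have a higher IBI coefficient of variation than NSR", {
  set.seed(3)
  rec <- render_beat_train(data.frame(class = c("NSR", "AFIB"),
                                      duration_s = c(30, 30)),
                           gen_params(nsr_bpm = 75, pac_rate = 0, pvc_rate = 0,
                                      aberration_rate = 0),
                           fs = 250)
  expect_equal(rec$rhythms$start, c(0, 7500))
  expect_equal(rec$rhythms$end, c(7500, 15000))
  cv <- function(b) { ib <- diff(b); sd(ib) / mean(ib) }
  nsr_cv <- cv(rec$beats$sample[rec$beats$sample < 7500])
  af_cv <- cv(rec$beats$sample[rec$beats$sample >= 7500])
  expect_gt(af_cv, nsr_cv)
})

test_that("rendering rejects degenerate plans", {
  expect_error(render_beat_train(data.frame(class = character(0),
                                            duration_s = numeric(0))),
               "non-empty")
  expect_error(render_beat_train(data.frame(class = "NSR", duration_s = -1)),
               "positive")
  expect_error(render_beat_train(data.frame(class = "XX", duration_s = 5)),
               "unknown rhythm")
})

test_that("generated recordings satisfy all invariants and tile exactly", {
  corpus <- tiny_corpus()
  for (rec in corpus$recordings) {
    expect_silent(validate_recording(rec))
    r <- rec$rhythms
    expect_equal(r$start[1], 0)
    expect_equal(r$end[nrow(r)], length(rec$signal))
    if (nrow(r) > 1) expect_equal(r$start[-1], r$end[-nrow(r)])
  }
})

test_that("upstream corpus has the requested shape and is seed-reproducible", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- generate_upstream_corpus(4, 2, 20, gen_params_separable(), seed = 1,
                                 dir = d1)
  c2 <- generate_upstream_corpus(4, 2, 20, gen_params_separable(), seed = 1,
                                 dir = d2)
  expect_length(c1$recordings, 8)
  expect_length(unique(c1$index$patient_id), 4)
  expect_identical(readLines(file.path(d1, "manifest.jsonl")),
                   readLines(file.path(d2, "manifest.jsonl")))
  for (i in seq_along(c1$recordings)) {
    expect_identical(c1$recordings[[i]]$beats, c2$recordings[[i]]$beats)
    expect_identical(c1$recordings[[i]]$signal, c2$recordings[[i]]$signal)
  }
  c3 <- generate_upstream_corpus(4, 2, 20, gen_params_separable(), seed = 2)
  expect_false(identical(c1$recordings[[1]]$signal, c3$recordings[[1]]$signal))
})

test_that("abnormal-beat rates match their binomial expectation", {
  all_nsr <- matrix(rep(c(1, 0, 0, 0), each = 4), 4,
                    dimnames = list(c("NSR", "AFIB", "AFLUT", "NOISE"),
                                    c("NSR", "AFIB", "AFLUT", "NOISE")))
  gp <- gen_params(pvc_rate = 0.1, pac_rate = 0, aberration_rate = 0,
                   nsr_bpm = 80, transition = all_nsr,
                   episode_mean_s = c(NSR = 120, AFIB = 1, AFLUT = 1, NOISE = 1))
  corpus <- generate_upstream_corpus(20, 1, 60, gp, seed = 9)
  cls <- unlist(lapply(corpus$recordings, function(r) r$beats$class))
  n <- length(cls)
  phat <- mean(cls == "PVC")
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(phat - 0.1), 3 * se)
})

test_that("single-label downstream sets follow the exact allocation rule", {
  dset <- generate_downstream_set(100, "cinc2017",
                                  class_ratios = c(NORMAL = .6, AF = .1,
                                                   OTHER = .2, NOISY = .1),
                                  seed = 7)
  labs <- vapply(dset$records, function(r) r$labels[1], "")
  expect_equal(as.integer(table(labs)[c("NORMAL", "AF", "OTHER", "NOISY")]),
               c(60L, 10L, 20L, 10L))
  durs <- vapply(dset$records, function(r) ncol(r$signal) / r$fs, 0)
  expect_true(all(durs >= 9 - 1e-6 & durs <= 60 + 1e-6))
  expect_true(all(vapply(dset$records, function(r) r$fs == 300, TRUE)))
  expect_error(generate_downstream_set(10, "bogus"), "arg")
})

test_that("12-lead multi-label records have shape (12, 5000) and labels", {
  dset <- generate_downstream_set(12, "multilabel12", seed = 3)
  for (r in dset$records) {
    expect_equal(dim(r$signal), c(12, 5000))
    expect_equal(r$fs, 500)
    expect_gte(length(r$labels), 1)
    expect_true(all(r$labels %in% dset$classes))
  }
})

test_that("AF records are more irregular than normal records by construction", {
  dset <- generate_downstream_set(40, "cinc2017",
                                  class_ratios = c(NORMAL = .5, AF = .5,
                                                   OTHER = 0, NOISY = 0),
                                  seed = 21)
  cvs <- vapply(dset$records, function(r) {
    ib <- diff(r$truth$beats$sample)
    sd(ib) / mean(ib)
  }, 0)
  labs <- vapply(dset$records, function(r) r$labels[1], "")
  expect_gt(mean(cvs[labs == "AF"]), mean(cvs[labs == "NORMAL"]))
})
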