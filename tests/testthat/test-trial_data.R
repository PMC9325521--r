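test_that("reader parses blanks as missing and preserves structure", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pid,group,u1,u2,c1,c2",
               "a,0,0.70,0.80,100,150",
               "b,0,0.60,,90,70",
               "c,1,0.55,0.65,120,200",
               "d,1,0.75,0.85,80,60"), f)
  schema <- list(id = "pid", arm = "group",
                 utilities = c("u1", "u2"), costs = c("c1", "c2"))
  d <- read_trial_data(f, schema, times = c(0, 0.5))
  expect_equal(n_participants(d), 4L)
  expect_equal(sum(is.na(d$utilities)), 1L)
  expect_true(is.na(d$utilities[2, 2]))
  expect_equal(sum(is.na(d$costs)), 0L)
  expect_equal(d$id, c("a", "b", "c", "d"))
})

test_that("reader rejects bad arm values, duplicates and non-numeric cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pid,group,u1,u2,c1,c2",
               "a,0,0.7,0.8,100,150",
               "b,2,0.6,0.5,90,70"), f)
  schema <- list(id = "pid", arm = "group",
                 utilities = c("u1", "u2"), costs = c("c1", "c2"))
  expect_error(read_trial_data(f, schema, c(0, 0.5)), "row 2")
  writeLines(c("pid,group,u1,u2,c1,c2",
               "a,0,0.7,0.8,100,150",
               "a,1,0.6,0.5,90,70"), f)
  expect_error(read_trial_data(f, schema, c(0, 0.5)), "duplicate")
  writeLines(c("pid,group,u1,u2,c1,c2",
               "a,0,0.7,abc,100,150",
               "b,1,0.6,0.5,90,70"), f)
  expect_error(read_trial_data(f, schema, c(0, 0.5)), "u2")
  expect_error(read_trial_data(f, schema, c(0, 0.25, 0.5)), "times")
})

test_that("a written synthetic trial round-trips with correct arm sizes", {
  out <- withr::local_tempdir()
  run_simulate("sadd_like", out, seed = 42)
  schema <- list(id = "id", arm = "arm",
                 utilities = paste0("u", 1:3), costs = paste0("c", 1:3))
  d <- read_trial_data(file.path(out, "observed.csv"), schema,
                       times = c(0, 0.25, 0.75))
  expect_equal(sum(d$arm == 0L), 111L)
  expect_equal(sum(d$arm == 1L), 108L)
  expect_false(any(is.na(d$utilities[, 1])))
  expect_false(any(is.na(d$costs[, 1])))
})

test_that("pattern table reproduces known pattern structure", {
  d <- make_table1_dataset()
  pt <- pattern_table(d)
  expect_equal(nrow(pt), 9L)
  expect_equal(pt$pattern[1], "------")
  expect_equal(pt$n_total[1], 101L)
  expect_equal(pt$pct_total[1], 46L)
  ref <- table1_patterns()
  m <- match(ref$pattern, pt$pattern)
  expect_equal(pt$n_control[m], ref$n_control)
  expect_equal(pt$n_intervention[m], ref$n_intervention)

  full <- complete_cases(d)
  ptf <- pattern_table(full)
  expect_equal(nrow(ptf), 1L)
  expect_equal(ptf$pct_total, 100L)
})

test_that("pattern counts match brute-force mask enumeration", {
  set.seed(31)
  for (rep in 1:5) {
    d <- rand_missing_dataset(n = 20, J = 3)
    pt <- pattern_table(d)
    # independent enumeration: count identical mask strings by hand
    masks <- apply(cbind(is.na(d$utilities), is.na(d$costs)), 1L,
                   function(m) paste(ifelse(m, "X", "-"), collapse = ""))
    for (i in seq_len(nrow(pt))) {
      expect_equal(pt$n_total[i], sum(masks == pt$pattern[i]))
    }
    expect_equal(sum(pt$n_control), sum(d$arm == 0L))
    expect_equal(sum(pt$n_intervention), sum(d$arm == 1L))
    expect_equal(sum(pt$n_total), n_participants(d))
  }
  # three participants with three distinct masks
  d3 <- trial_dataset(1:3, c(0, 1, 1),
                      rbind(c(0.7, NA), c(0.6, 0.5), c(NA, 0.4)),
                      rbind(c(10, 20), c(30, NA), c(50, 60)),
                      times = c(0, 0.5))
  pt3 <- pattern_table(d3)
  expect_equal(nrow(pt3), 3L)
  expect_equal(pt3$n_total, c(1L, 1L, 1L))
})

test_that("complete_cases retains completers and is idempotent", {
  d <- make_table1_dataset()
  cc <- complete_cases(d)
  expect_equal(n_participants(cc), 101L)
  expect_false(anyNA(cc$utilities))
  expect_false(anyNA(cc$costs))
  expect_identical(complete_cases(cc)$id, cc$id)

  # fully observed data are untouched
  expect_identical(complete_cases(cc)$utilities, cc$utilities)

  # one arm with zero completers is an error
  bad <- trial_dataset(1:4, c(0, 0, 1, 1),
                       rbind(c(0.7, 0.8), c(0.6, 0.5),
                             c(0.4, NA), c(0.3, NA)),
                       matrix(10, 4, 2), times = c(0, 0.5))
  expect_error(complete_cases(bad), "complete cases")
})

test_that("observed summaries use available cases only", {
  d <- trial_dataset(1:4, c(0, 0, 0, 1),
                     rbind(c(0.6, NA, NA), c(0.8, 0.9, NA),
                           c(0.7, 0.5, NA), c(0.5, 0.5, 0.5)),
                     matrix(100, 4, 3), times = c(0, 0.25, 0.75))
  s <- observed_summary(d)
  u0 <- s[s$outcome == "utility" & s$arm == 0, ]
  expect_equal(u0$mean[u0$time == 0.25], 0.7)
  expect_equal(u0$n[u0$time == 0.25], 2L)
  # all-missing cell: NA summary, n = 0, no crash
  expect_true(is.na(u0$mean[u0$time == 0.75]))
  expect_equal(u0$n[u0$time == 0.75], 0L)

  # naive loop oracle on complete data
  set.seed(8)
  dc <- rand_missing_dataset(16, 3)
  s2 <- observed_summary(dc)
  for (a in 0:1) for (j in 1:3) {
    v <- dc$utilities[dc$arm == a, j]
    v <- v[!is.na(v)]
    row <- s2[s2$outcome == "utility" & s2$arm == a &
                s2$time == dc$times[j], ]
    expect_equal(row$mean, mean(v))
    expect_equal(row$sd, sd(v))
    expect_equal(row$n, length(v))
  }
})

test_that("generator sample means sit near configured means", {
  cfg <- synthetic_config(n = c(3000, 3000))
  d <- generate_trial(cfg, seed = 12)$complete
  s <- observed_summary(d)
  for (a in 0:1) for (j in 1:3) {
    row <- s[s$outcome == "utility" & s$arm == a & s$time == cfg$times[j], ]
    mc_se <- cfg$utility_sd[a + 1, j] / sqrt(3000)
    expect_lt(abs(row$mean - cfg$utility_mean[a + 1, j]), 3 * mc_se)
  }
})

test_that("long-format input converts to the wide representation", {
  long <- data.frame(
    id = rep(c("x", "y"), each = 2),
    arm = rep(c(0, 1), each = 2),
    time = rep(c(0, 0.5), 2),
    utility = c(0.7, 0.8, 0.6, NA),
    cost = c(10, 20, 30, 40))
  d <- long_to_trial_data(long, times = c(0, 0.5))
  expect_equal(d$utilities, cbind(u1 = c(0.7, 0.6), u2 = c(0.8, NA)))
  expect_equal(d$costs[2, 2], c(c2 = 40))
})
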