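test_that("kinetics write/read round trip is the identity", {
  s1 <- simulate_curve("A", "ctrl30", 1, run_hours = 6, noise_sd = 2,
                       seed = 11)
  s2 <- simulate_curve("A", "sorb10", 1, run_hours = 6, theta = 0.4,
                       noise_sd = 2, seed = 12)
  s3 <- simulate_curve("B", "ctrl30", 2, run_hours = 6, noise_sd = 0)
  path <- tempfile(fileext = ".tsv")
  write_kinetics(list(s1, s2, s3), path)
  back <- read_kinetics(path)
  expect_length(back, 3L)
  expect_setequal(names(back),
                  vapply(list(s1, s2, s3), pmscreen:::series_key,
                         character(1)))
  for (s in list(s1, s2, s3)) {
    b <- back[[pmscreen:::series_key(s)]]
    expect_equal(b$times, s$times, tolerance = 1e-12)
    expect_equal(b$signals, s$signals, tolerance = 1e-6)
  }
})

test_that("a 96 h run at 15-min sampling yields 385 time points", {
  s <- simulate_curve("A", "ctrl30", 1, run_hours = 96)
  expect_length(s$times, 385L)
  path <- tempfile(fileext = ".tsv")
  write_kinetics(list(s), path)
  expect_length(read_kinetics(path)[[1]]$times, 385L)
})

test_that("malformed kinetic files fail with errors naming the offender", {
  # non-uniform grid
  bad <- write_fixture(c("strain\tcondition\treplicate\ttime_h\tsignal",
                         "A\tc1\t1\t0\t1", "A\tc1\t1\t0.25\t2",
                         "A\tc1\t1\t0.75\t3"))
  expect_error(read_kinetics(bad), "A/c1/rep1.*non-uniform")
  # duplicate time row
  dup <- write_fixture(c("strain\tcondition\treplicate\ttime_h\tsignal",
                         "B\tc1\t1\t0\t1", "B\tc1\t1\t0\t2",
                         "B\tc1\t1\t0.25\t3"))
  expect_error(read_kinetics(dup), "duplicate.*B/c1/rep1")
  # missing column under the schema
  nocol <- write_fixture(c("strain\tcondition\treplicate\thours\tsignal",
                           "A\tc1\t1\t0\t1"))
  expect_error(read_kinetics(nocol), "time_h")
})

test_that("read_kinetics returns one series per distinct triple", {
  lines <- c("strain,condition,replicate,time_h,signal")
  for (st in c("A", "B")) for (r in 1:3)
    lines <- c(lines, paste(st, "c1", r, c(0, 0.25, 0.5),
                            c(1, 2, 3), sep = ","))
  out <- read_kinetics(write_fixture(lines, ".csv"))
  expect_length(out, 6L)
})

test_that("condition tables validate controls, endpoints and defaults", {
  path <- write_fixture(c(
    "condition_id\tstressor\tdose\tunit\ttemperature_C\tendpoint_hours\tcontrol_id",
    "ctrl30\tglucose\t6\t%w/v\t30\t50\t",
    "ctrl40\tglucose\t6\t%w/v\t40\tNA\t",
    "sorb10\tsorbitol\t10\t%w/v\t30\t50\tctrl30",
    "heat40\ttemperature\t0\t\t40\t24\tctrl40"))
  conds <- read_conditions(path)
  expect_s3_class(conds, "pm_conditions")
  expect_equal(conds$endpoint_hours[conds$condition_id == "heat40"], 24)
  # NA endpoint defaults to 24 h at 40 degrees
  expect_equal(conds$endpoint_hours[conds$condition_id == "ctrl40"], 24)

  dangling <- write_fixture(c(
    "condition_id\tstressor\tdose\tunit\ttemperature_C\tendpoint_hours\tcontrol_id",
    "sorb10\tsorbitol\t10\t%w/v\t30\t50\tmissing"))
  expect_error(read_conditions(dangling), "unknown control_id")

  zero_ep <- write_fixture(c(
    "condition_id\tstressor\tdose\tunit\ttemperature_C\tendpoint_hours\tcontrol_id",
    "ctrl30\tglucose\t6\t%w/v\t30\t0\t"))
  expect_error(read_conditions(zero_ep), "endpoint_hours")
})

test_that("strain tables enforce unique non-empty ids", {
  ok <- write_fixture(c("strain_id\tspecies\torigin",
                        "S288C\tS. cerevisiae\tlab",
                        "N-17\tS. paradoxus\twild"))
  expect_equal(nrow(read_strains(ok)), 2L)
  dup <- write_fixture(c("strain_id\tspecies\torigin",
                         "S288C\tS. cerevisiae\tlab",
                         "S288C\tS. cerevisiae\tlab"))
  expect_error(read_strains(dup), "duplicate strain_id")
  odd <- write_fixture(c("strain_id\tspecies\torigin",
                         "X1\tS. weirdus\tunknown"))
  expect_warning(read_strains(odd), "controlled vocabulary")
})

test_that("tolerance tables serialise deterministically and round trip", {
  scores <- data.frame(
    strain_id = c("B", "A", "C", "A"),
    condition_id = c("eth10", "eth10", "eth10", "sorb10"),
    rsi_stress = c(48.123456, 30.5, 10.987654321, 55),
    rsi_control = c(60.1, 61.2, 59.9, 60),
    percent_rsi = c(80.072306, 49.836601, 18.34333, 91.666667),
    low_control = c(FALSE, FALSE, FALSE, FALSE))
  class(scores) <- c("pm_scores", "data.frame")
  path <- tempfile(fileext = ".tsv")
  write_tolerance_table(scores, path)
  lines <- readLines(path)
  expect_equal(lines[1],
    "strain_id\tcondition_id\trsi_stress\trsi_control\tpercent_rsi\tlow_control_flag")
  expect_length(lines, 5L)
  # grouped by condition, descending percent_rsi within
  conds <- vapply(strsplit(lines[-1], "\t"), `[`, character(1), 2L)
  expect_equal(conds, c("eth10", "eth10", "eth10", "sorb10"))
  back <- read_tolerance_table(path)
  o <- order(scores$condition_id, -scores$percent_rsi, scores$strain_id)
  expect_equal(back$percent_rsi, signif(scores$percent_rsi[o], 6),
               tolerance = 1e-9)
  expect_equal(back$rsi_stress, signif(scores$rsi_stress[o], 6),
               tolerance = 1e-9)
  # single score gives header + one row
  one <- tempfile(fileext = ".tsv")
  write_tolerance_table(scores[1, ], one)
  expect_length(readLines(one), 2L)
})
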