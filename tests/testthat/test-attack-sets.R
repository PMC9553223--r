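pop40 <- random_discrete_table(40, c(3, 4), seed = 1)
pop40$ids <- sprintf("id%02d", 1:40)

test_that("drawing the real sample is a reproducible SRSWOR with ids", {
  s1 <- draw_real_sample(pop40, 10, seed = 9)
  s2 <- draw_real_sample(pop40, 10, seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$data), 10)
  expect_true(all(s1$ids %in% pop40$ids))
  census <- draw_real_sample(pop40, 40, seed = 2)
  expect_setequal(census$ids, pop40$ids)
  expect_error(draw_real_sample(pop40, 41, seed = 1), "n <= N")
  noid <- drop_ids(pop40)
  expect_error(draw_real_sample(noid, 5, seed = 1), "ids")
})

test_that("splitting the real dataset is a disjoint exhaustive partition", {
  real <- draw_real_sample(pop40, 20, seed = 3)
  parts <- split_real(real, holdout_fraction = 0.5, seed = 4)
  expect_equal(nrow(parts$training$data), 10)
  expect_equal(nrow(parts$holdout$data), 10)
  expect_length(intersect(parts$training$ids, parts$holdout$ids), 0)
  expect_setequal(c(parts$training$ids, parts$holdout$ids), real$ids)
  expect_error(split_real(real, 1.5, 1), "holdout_fraction")
})

test_that("odd split sizes round half away from zero", {
  pop <- random_discrete_table(101, c(3), seed = 5)
  pop$ids <- as.character(1:101)
  parts <- split_real(pop, holdout_fraction = 0.5, seed = 1)
  expect_equal(nrow(parts$training$data), 51) # round(50.5) away from zero
  expect_equal(nrow(parts$holdout$data), 50)
})

test_that("partition attack composition is exact: round(m*t) members, shuffled", {
  real <- draw_real_sample(pop40, 30, seed = 7)
  parts <- split_real(real, 0.5, seed = 8)
  for (t in c(0, 0.25, 0.5, 0.77, 1)) {
    design <- sampling_design(n = 30, N = 40, m = 12, t = t, seed = 99)
    atk <- build_partition_attack(parts$training, parts$holdout, design)
    expect_length(atk$member, 12)
    expect_equal(sum(atk$member), round(12 * t + 1e-9))
    expect_true(all(atk$records$ids[atk$member] %in% parts$training$ids))
    expect_true(all(atk$records$ids[!atk$member] %in% parts$holdout$ids))
    expect_false(anyDuplicated(atk$records$ids) > 0)
  }
  too_big <- sampling_design(n = 30, N = 40, m = 40, t = 1, seed = 1)
  expect_error(build_partition_attack(parts$training, parts$holdout, too_big),
               "training sample too small")
})

test_that("ground-truth attack labels membership by identity", {
  real <- draw_real_sample(pop40, 15, seed = 10)
  # census attack: label count is exactly n
  atk <- build_ground_truth_attack(pop40, real$ids, m = 40, seed = 11)
  expect_equal(sum(atk$member), 15)
  # population = real dataset: everyone is a member
  atk2 <- build_ground_truth_attack(real, real$ids, m = 10, seed = 12)
  expect_true(all(atk2$member))
  expect_error(build_ground_truth_attack(pop40, c("nope"), m = 5, seed = 1), "subset")
  expect_error(build_ground_truth_attack(pop40, real$ids, m = 41, seed = 1), "m <= N")
})

test_that("ground-truth member counts follow the hypergeometric overlap mean", {
  # small-scale replicate check; the full-scale one lives in the acceptance suite
  pop <- random_discrete_table(500, c(3), seed = 13)
  pop$ids <- as.character(1:500)
  real <- draw_real_sample(pop, 100, seed = 14)
  counts <- vapply(1:200, function(i) {
    sum(build_ground_truth_attack(pop, real$ids, m = 50, seed = 1000 + i)$member)
  }, numeric(1))
  model <- overlap_model(N = 500, n = 100, m = 50)
  se <- sqrt(50 * 0.2 * 0.8 * (500 - 50) / (500 - 1)) / sqrt(200)
  expect_lt(abs(mean(counts) - expected_overlap(model)), 3 * se)
})

test_that("attack scoring reproduces hand counts and the naive ceiling", {
  real <- draw_real_sample(pop40, 10, seed = 15)
  design <- sampling_design(n = 10, N = 40, m = 4, t = 0.5, seed = 1)
  atk <- attack_set(subset_rows(pop40, 1:4), member = c(TRUE, TRUE, FALSE, TRUE))
  outcome <- data.frame(min_distance = c(0, 1, 0, 6),
                        matched = c(TRUE, TRUE, TRUE, FALSE))
  s <- score_attack(outcome, atk, design)
  expect_equal(s$precision, 2 / 3)
  expect_equal(s$recall, 2 / 3)
  expect_equal(s$f1, 2 / 3)
  # everything-matches outcome at member fraction q reproduces f1(q, 1)
  all_match <- data.frame(min_distance = rep(0, 4), matched = rep(TRUE, 4))
  s2 <- score_attack(all_match, atk, design)
  expect_equal(s2$precision, 3 / 4)
  expect_equal(s2$recall, 1)
  expect_equal(s2$f1, f1_score(3 / 4, 1))
  # no members at all: recall defined as 0 with a warning
  none <- attack_set(subset_rows(pop40, 1:4), member = rep(FALSE, 4))
  expect_warning(s3 <- score_attack(all_match, none, design), "no training members")
  expect_equal(s3$f1, 0)
})

test_that("everything-matches scoring attains Fmax when the label fraction is n/N", {
  # attack set whose member fraction equals the sampling fraction 10/40
  atk <- attack_set(subset_rows(pop40, 1:8), member = rep(c(TRUE, FALSE), c(2, 6)))
  design <- sampling_design(n = 10, N = 40, m = 8, t = 0.25, seed = 1)
  all_match <- data.frame(min_distance = rep(0, 8), matched = rep(TRUE, 8))
  s <- score_attack(all_match, atk, design)
  expect_equal(s$f1, f_max(10, 40), tolerance = 1e-12)
  expect_equal(s$m_score, 0, tolerance = 1e-12)
})

test_that("attack sets serialize to CSV with the member column", {
  atk <- attack_set(subset_rows(pop40, 1:3), member = c(TRUE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_attack_set(atk, path)
  back <- utils::read.csv(path)
  expect_equal(back$member, c(TRUE, FALSE, TRUE))
  expect_equal(nrow(back), 3)
})
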