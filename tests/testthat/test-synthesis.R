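test_that("generated tables carry the training schema and no identifiers", {
  train <- random_discrete_table(60, c(3, 4, 2), seed = 1)
  train$ids <- as.character(1:60)
  model <- fit_sequential_trees(train)
  expect_error(generate(model, 0), "positive")
  syn <- generate(model, 25, seed = 2)
  expect_equal(nrow(syn$data), 25)
  expect_equal(names(syn$data), names(train$data))
  expect_null(syn$ids)
  expect_true(all(unlist(syn$data) %in% unlist(train$data)))
})

test_that("fitting and generation are deterministic under a fixed seed", {
  train <- random_discrete_table(80, c(4, 3), seed = 3)
  m1 <- fit_sequential_trees(train, synthesizer_spec(seed = 7))
  m2 <- fit_sequential_trees(train, synthesizer_spec(seed = 7))
  expect_equal(m1$parts[[1]], m2$parts[[1]])
  expect_identical(generate(m1, 50, seed = 5)$data, generate(m2, 50, seed = 5)$data)
  expect_false(identical(generate(m1, 50, seed = 5)$data, generate(m1, 50, seed = 6)$data))
})

test_that("a single-column model is the empirical marginal, for both methods", {
  df <- data.frame(a = rep(c("A", "B"), times = c(70, 30)))
  train <- make_discrete_table(df)
  seq_m <- fit_sequential_trees(train)
  ind_m <- fit_independent_marginals(train)
  expect_equal(seq_m$parts[[1]], ind_m$parts[[1]])
  expect_equal(sort(seq_m$parts[[1]]$probs), c(0.3, 0.7))
  # 10,000 generated rows reproduce the marginal within 3 binomial SEs
  syn <- generate(seq_m, 10000, seed = 4)
  p_hat <- mean(syn$data$a == "A")
  se <- sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(p_hat - 0.7), 3 * se)
})

test_that("a deterministic dependency is reproduced exactly by the trees", {
  # B is a function of A, with ample rows per leaf
  set.seed(8)
  a <- sample(paste0("a", 1:4), 400, replace = TRUE)
  f <- c(a1 = "b2", a2 = "b1", a3 = "b2", a4 = "b3")
  train <- make_discrete_table(data.frame(a = a, b = unname(f[a])))
  model <- fit_sequential_trees(train)
  syn <- generate(model, 1000, seed = 9)
  expect_true(all(syn$data$b == f[syn$data$a]))
})

test_that("independent marginals destroy association that sequential trees keep", {
  # strongly coupled pair
  set.seed(10)
  a <- sample(paste0("a", 1:3), 600, replace = TRUE)
  b <- ifelse(runif(600) < 0.9, paste0("b", match(a, paste0("a", 1:3))),
              sample(paste0("b", 1:3), 600, replace = TRUE))
  train <- make_discrete_table(data.frame(a = a, b = b))
  syn_seq <- generate(fit_sequential_trees(train), 2000, seed = 11)
  syn_ind <- generate(fit_independent_marginals(train), 2000, seed = 12)
  chi <- function(tab) suppressWarnings(
    stats::chisq.test(table(tab$data$a, tab$data$b))$statistic)
  expect_gt(chi(syn_seq), 10 * chi(syn_ind))
  expect_gt(stats::chisq.test(table(syn_ind$data$a, syn_ind$data$b))$p.value, 0.001)
})

test_that("copy returns training rows verbatim and sentinel never overlaps them", {
  train <- random_discrete_table(12, c(3, 3), seed = 13)
  train$ids <- as.character(1:12)
  copy_m <- fit_synthesizer(train, synthesizer_spec("copy"))
  syn <- generate(copy_m, 12)
  expect_equal(syn$data, drop_ids(discretize(train))$data)
  expect_null(syn$ids)
  sent <- generate(fit_synthesizer(train, synthesizer_spec("sentinel")), 5)
  expect_equal(nrow(sent$data), 5)
  expect_true(all(sent$data == "##sentinel##"))
  out <- match_attack_set(discretize(train), sent, match_config(0))
  expect_false(any(out$matched))
})

test_that("continuous training columns are binned and cut-points travel with the model", {
  schema <- table_schema(column_schema("g", "categorical"),
                         column_schema("x", "numeric", bins = 4))
  set.seed(14)
  train <- record_table(data.frame(g = sample(c("u", "v"), 100, TRUE), x = rnorm(100)),
                        schema)
  model <- fit_sequential_trees(train)
  expect_named(model$cutpoints, "x")
  syn <- generate(model, 30, seed = 15)
  expect_false(has_continuous_columns(syn))
  expect_equal(syn$cutpoints, model$cutpoints)
})

test_that("empty training tables and bad visit orders are rejected", {
  train <- random_discrete_table(10, c(2, 2), seed = 16)
  empty <- subset_rows(train, integer(0))
  expect_error(fit_sequential_trees(empty), "empty")
  expect_error(fit_sequential_trees(train, synthesizer_spec(visit_order = c("c1", "nope"))),
               "permutation")
  # reversed visit order is accepted and respected
  rev_m <- fit_sequential_trees(train, synthesizer_spec(visit_order = c("c2", "c1")))
  expect_equal(rev_m$order_idx, c(2L, 1L))
  expect_equal(names(generate(rev_m, 5)$data), c("c1", "c2"))
})
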