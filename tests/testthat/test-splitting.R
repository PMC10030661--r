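# BP class encoding, subject label matrices, iterative stratification,
# holdout, leaked splits and the split audit.

test_that("BP class encoding uses the published cut points, half-open", {
  expect_identical(encode_bp_class(95, 70)$sbp_class, 1L)
  expect_identical(encode_bp_class(120, 85)$dbp_class, 3L)
  expect_identical(encode_bp_class(140, 70)$sbp_class, 3L)   # boundary
  expect_identical(encode_bp_class(100, 60)$sbp_class, 2L)
  expect_identical(encode_bp_class(100, 60)$dbp_class, 2L)
  expect_identical(encode_bp_class(165, 105)$joint_class, 16L)
  expect_identical(encode_bp_class(95, 55)$joint_class, 1L)
  # exactly 16 distinct joint classes over a dense label grid
  grid <- expand.grid(sbp = seq(80, 200, by = 1), dbp = seq(40, 120, by = 1))
  enc <- encode_bp_class(grid$sbp, grid$dbp)
  expect_identical(sort(unique(enc$joint_class)), 1:16)
  expect_identical(enc$joint_class,
                   4L * (enc$sbp_class - 1L) + enc$dbp_class)
  expect_error(encode_bp_class(NaN, 70), "non-finite")
})

test_that("subject matrix tallies joint classes exactly", {
  df <- data.frame(subject_id = c("a", "a", "a", "b"),
                   sbp = c(120, 120, 120, 150), dbp = c(70, 70, 70, 85))
  m <- build_subject_matrix(df)
  expect_identical(dim(m), c(2L, 16L))
  expect_identical(m["a", "class6"], 3L)   # sbp class 2, dbp class 2
  expect_identical(sum(m["a", ]), 3L)
  expect_identical(sum(m["b", ]), 1L)
  # brute-force tally oracle on a random cohort
  set.seed(1)
  df2 <- data.frame(subject_id = sample(letters[1:6], 60, TRUE),
                    sbp = runif(60, 85, 190), dbp = runif(60, 45, 110))
  m2 <- build_subject_matrix(df2)
  enc <- encode_bp_class(df2$sbp, df2$dbp)
  for (i in seq_len(60)) {
    expect_gte(m2[df2$subject_id[i], enc$joint_class[i]], 1L)
  }
  expect_identical(unname(rowSums(m2)[sort(unique(df2$subject_id))]),
                   as.numeric(table(df2$subject_id)))
  expect_error(build_subject_matrix(data.frame(subject_id = "a", sbp = NA,
                                               dbp = 70)), "missing")
})

test_that("stratified subject k-fold partitions subjects evenly and leak-free", {
  m <- matrix(0L, 10, 16, dimnames = list(paste0("s", 1:10),
                                          paste0("class", 1:16)))
  m[, 6] <- 3L   # identical label rows
  fa <- stratified_subject_kfold(m, K = 5, seed = 1)
  expect_true(all(table(fa$assignment) == 2))
  expect_identical(fa$leakage_fraction, 0)
  expect_setequal(names(fa$assignment), rownames(m))
  # deterministic under a fixed seed
  fa2 <- stratified_subject_kfold(m, K = 5, seed = 1)
  expect_identical(fa$assignment, fa2$assignment)
  expect_error(stratified_subject_kfold(m, K = 20, seed = 1), "subjects")
})

test_that("stratification beats the median uniform-random subject split", {
  # skewed cohort: ~5% of subjects carry the rare high-pressure class
  set.seed(3)
  n_sub <- 60
  subj <- sprintf("s%02d", 1:n_sub)
  rare <- subj[1:3]
  rows <- lapply(subj, function(s) {
    n_seg <- 6
    if (s %in% rare) {
      data.frame(subject_id = s, sbp = runif(n_seg, 165, 190),
                 dbp = runif(n_seg, 102, 112))
    } else {
      data.frame(subject_id = s, sbp = runif(n_seg, 105, 135),
                 dbp = runif(n_seg, 62, 78))
    }
  })
  df <- do.call(rbind, rows)
  m <- build_subject_matrix(df)
  fa <- stratified_subject_kfold(m, K = 5, seed = 11)
  tv_strat <- max(audit_split(fa, df)$tv_distance)
  tv_rand <- vapply(1:100, function(s) {
    rnd <- withr::with_seed(s, setNames(sample(rep_len(1:5, n_sub)), subj))
    fa_r <- bpbench:::new_fold_assignment(rnd, 5, "subject", s)
    max(audit_split(fa_r, df)$tv_distance)
  }, numeric(1))
  expect_lte(tv_strat, median(tv_rand))
})

test_that("holdout split respects fractions and flags pseudo-subjects", {
  m <- matrix(0L, 100, 16, dimnames = list(sprintf("s%03d", 1:100),
                                           paste0("class", 1:16)))
  m[, 6] <- 2L
  fa <- holdout_split(m, c(train = 0.6, validation = 0.2, test = 0.2),
                      seed = 2)
  expect_identical(as.integer(table(factor(fa$assignment, levels = 1:3))),
                   c(60L, 20L, 20L))
  # partition: each subject in exactly one set
  expect_identical(length(fa$assignment), 100L)
  expect_false(anyNA(fa$assignment))
  expect_error(holdout_split(m, c(0.5, 0.5, 0)), "positive")
  expect_message(holdout_split(m, c(a = 0.5, b = 0.5), seed = 1,
                               pseudo_subjects = TRUE), "pseudo-subjects")
})

test_that("leaked split leaks almost surely with many segments per subject", {
  recs_df <- data.frame(subject_id = rep(sprintf("s%02d", 1:12), each = 8),
                        sbp = 120, dbp = 70)
  fa <- leaked_split(recs_df, K = 5, seed = 4)
  expect_gt(fa$leakage_fraction, 0.99)
  # one segment per subject: leakage impossible
  solo <- data.frame(subject_id = sprintf("s%02d", 1:20), sbp = 120, dbp = 70)
  expect_identical(leaked_split(solo, K = 5, seed = 4)$leakage_fraction, 0)
  # reproducible
  expect_identical(leaked_split(recs_df, 5, seed = 9)$assignment,
                   leaked_split(recs_df, 5, seed = 9)$assignment)
})

test_that("split audit reconciles histograms and leakage", {
  df <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 5),
                   sbp = rep(c(120, 150, 95, 170), each = 5),
                   dbp = rep(c(70, 85, 55, 105), each = 5))
  m <- build_subject_matrix(df)
  fa <- stratified_subject_kfold(m, K = 2, seed = 1)
  aud <- audit_split(fa, df)
  expect_identical(aud$leakage_fraction, 0)
  expect_identical(sum(aud$joint_class_counts), 20)
  expect_identical(unname(rowSums(aud$sbp_class_counts)), unname(aud$fold_sizes))
  expect_error(audit_split(fa, transform(df, subject_id = paste0("x", subject_id))),
               "missing subjects")
})

test_that("input order does not change the stratified assignment", {
  set.seed(8)
  df <- data.frame(subject_id = rep(sprintf("s%02d", 1:15), each = 4),
                   sbp = runif(60, 90, 180), dbp = runif(60, 50, 110))
  fa1 <- stratified_subject_kfold(build_subject_matrix(df), 3, seed = 6)
  df_sh <- df[withr::with_seed(1, sample(nrow(df))), ]
  fa2 <- stratified_subject_kfold(build_subject_matrix(df_sh), 3, seed = 6)
  expect_identical(fa1$assignment, fa2$assignment)
})
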