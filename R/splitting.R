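# Subject-grouped multi-label stratified splitting: 4x4 BP class encoding,
# per-subject label-combination counts, greedy iterative stratification for
# K-fold and weighted holdout splits, the deliberately-leaky uniform
# segment split, and the split audit.

#' Encode SBP/DBP into the 4x4 joint class grid
#'
#' SBP classes: (1) below 100, (2) 100-140, (3) 140-160, (4) over 160 mmHg.
#' DBP classes: (1) below 60, (2) 60-80, (3) 80-100, (4) over 100 mmHg.
#' Boundaries use the half-open convention \[lo, hi), so SBP 140 is class 3.
#' The joint class is `4 * (sbp_class - 1) + dbp_class` (16 possibilities).
#'
#' @param sbp,dbp Numeric vectors in mmHg (finite).
#' @return Data frame with `sbp_class`, `dbp_class`, `joint_class`.
#' @export
encode_bp_class <- function(sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp))) {
    stop_spec("encode_bp_class: non-finite blood pressure value")
  }
  sc <- findInterval(sbp, c(100, 140, 160)) + 1L
  dc <- findInterval(dbp, c(60, 80, 100)) + 1L
  data.frame(sbp_class = sc, dbp_class = dc,
             joint_class = 4L * (sc - 1L) + dc)
}

segments_meta <- function(segments) {
  do.call(rbind, lapply(segments, function(s) {
    data.frame(subject_id = s$subject_id, record_id = s$record_id,
               sbp = s$sbp_label, dbp = s$dbp_label,
               stringsAsFactors = FALSE)
  }))
}

#' Per-subject counts over the 16 joint BP classes
#'
#' @param segments List of labelled `bp_segment` objects, or a data frame
#'   with columns `subject_id`, `sbp`, `dbp`.
#' @return Integer matrix, one row per subject (rownames = subject ids), 16
#'   columns; row sums equal the subjects' segment counts.
#' @export
build_subject_matrix <- function(segments) {
  df <- if (is.data.frame(segments)) segments else segments_meta(segments)
  if (anyNA(df$sbp) || anyNA(df$dbp)) {
    stop_spec("build_subject_matrix: segments with missing SBP/DBP labels")
  }
  enc <- encode_bp_class(df$sbp, df$dbp)
  subjects <- sort(unique(df$subject_id))
  m <- matrix(0L, nrow = length(subjects), ncol = 16L,
              dimnames = list(subjects, paste0("class", 1:16)))
  for (i in seq_len(nrow(df))) {
    m[df$subject_id[i], enc$joint_class[i]] <- m[df$subject_id[i], enc$joint_class[i]] + 1L
  }
  m
}

new_fold_assignment <- function(assignment, K, by, seed,
                                fold_class_counts = NULL,
                                leakage_fraction = NA_real_) {
  structure(list(assignment = assignment, K = K, by = by, seed = seed,
                 fold_class_counts = fold_class_counts,
                 leakage_fraction = leakage_fraction),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment: %d %ss in %d folds (%s), leakage %.3f>\n",
              length(x$assignment), x$by, x$K,
              paste(table(x$assignment), collapse = "/"),
              x$leakage_fraction))
  invisible(x)
}

# Core greedy iterative stratification over subjects with class-count rows.
# weights: fold proportions (length K, sum 1).
iterative_stratify <- function(matrix, weights, seed) {
  K <- length(weights)
  subjects <- rownames(matrix)
  n_sub <- length(subjects)
  if (n_sub < K) stop_spec("need at least as many subjects (%d) as folds (%d)", n_sub, K)
  with_seed(seed, {
    remaining <- matrix
    # per-fold desired counts of each class, and desired total sizes
    desire <- outer(weights, colSums(matrix))
    cap <- weights * sum(matrix)
    fold_of <- setNames(rep(NA_integer_, n_sub), subjects)
    unassigned <- rep(TRUE, n_sub)
    while (any(unassigned)) {
      tot <- colSums(remaining[unassigned, , drop = FALSE])
      active <- which(tot > 0)
      if (length(active) == 0L) {
        # subjects with all-zero rows: place by remaining capacity
        for (i in which(unassigned)) {
          f <- which.max(cap + runif(K) * 1e-9)
          fold_of[i] <- f
          cap[f] <- cap[f] - sum(matrix[i, ])
          unassigned[i] <- FALSE
        }
        break
      }
      # rarest remaining class first
      l <- active[which.min(tot[active])]
      cand <- which(unassigned & matrix[, l] > 0)
      # within it, the subject with most examples of that class
      i <- cand[order(-matrix[cand, l], runif(length(cand)))[1]]
      # fold with the largest remaining desideratum for that class;
      # ties by remaining capacity, then seeded randomness
      f <- order(-desire[, l], -cap, runif(K))[1]
      fold_of[i] <- f
      desire[f, ] <- desire[f, ] - matrix[i, ]
      cap[f] <- cap[f] - sum(matrix[i, ])
      unassigned[i] <- FALSE
      remaining[i, ] <- 0L
    }
    fold_of
  })
}

fold_class_counts <- function(matrix, fold_of, K) {
  t(vapply(seq_len(K), function(f) {
    rows <- names(fold_of)[fold_of == f]
    colSums(matrix[rows, , drop = FALSE])
  }, numeric(ncol(matrix))))
}

#' Subject-grouped stratified K-fold assignment
#'
#' Greedy iterative multi-label stratification over subjects weighted by
#' their 16-class joint BP count rows: the rarest remaining class is placed
#' first, within it the subject holding most of it, into the fold with the
#' largest remaining desideratum for that class (ties by remaining fold
#' capacity, then seeded randomness). All segments of a subject share a
#' fold, so subject leakage is zero by construction.
#'
#' @param matrix Subject-by-class count matrix from [build_subject_matrix()].
#' @param K Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A `fold_assignment` (subject-keyed).
#' @export
stratified_subject_kfold <- function(matrix, K, seed = 1L) {
  if (K < 2L) stop_spec("K must be >= 2")
  fold_of <- iterative_stratify(matrix, rep(1 / K, K), seed)
  new_fold_assignment(fold_of, K, by = "subject", seed = seed,
                      fold_class_counts = fold_class_counts(matrix, fold_of, K),
                      leakage_fraction = 0)
}

#' Stratified holdout (train/validation/test) split
#'
#' One stratified three-way (or n-way) split produced by the same iterative
#' stratification engine with unequal fold weights. When subject identifiers
#' are unavailable, pass a matrix built with record ids as pseudo-subjects;
#' this is logged as a known leakage caveat.
#'
#' @param matrix Subject-by-class count matrix.
#' @param fractions Positive fold fractions summing to 1, e.g.
#'   `c(train = 0.6, validation = 0.2, test = 0.2)`.
#' @param seed Integer seed.
#' @param pseudo_subjects Set `TRUE` when rows are records standing in for
#'   unknown subjects; emits a prominent message.
#' @return A `fold_assignment` with named fold levels.
#' @export
holdout_split <- function(matrix, fractions = c(train = 0.6, validation = 0.2,
                                                test = 0.2),
                          seed = 1L, pseudo_subjects = FALSE) {
  if (any(fractions <= 0)) stop_spec("holdout_split: all fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-8) stop_spec("holdout_split: fractions must sum to 1")
  if (pseudo_subjects) {
    message("holdout_split: records treated as pseudo-subjects; ",
            "subject leakage between sets cannot be ruled out")
  }
  fold_of <- iterative_stratify(matrix, as.numeric(fractions), seed)
  fa <- new_fold_assignment(fold_of, length(fractions), by = "subject",
                            seed = seed,
                            fold_class_counts = fold_class_counts(matrix, fold_of,
                                                                  length(fractions)),
                            leakage_fraction = if (pseudo_subjects) NA_real_ else 0)
  fa$fold_names <- names(fractions)
  fa
}

#' Uniform segment-level (leaky) fold assignment
#'
#' The deliberately wrong baseline: segments — not subjects — are assigned
#' uniformly at random to K folds, so segments of one subject straddle
#' folds. The returned `leakage_fraction` is the fraction of segments whose
#' subject also appears in at least one other fold (i.e. in the training
#' partition when that fold is the test set).
#'
#' @param segments List of `bp_segment`s or a data frame with `subject_id`.
#' @param K Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A `fold_assignment` (segment-keyed; `assignment[i]` is the fold
#'   of segment `i`).
#' @export
leaked_split <- function(segments, K, seed = 1L) {
  if (K < 2L) stop_spec("K must be >= 2")
  df <- if (is.data.frame(segments)) segments else segments_meta(segments)
  n <- nrow(df)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(K), n)))
  leak <- vapply(seq_len(n), function(i) {
    any(df$subject_id == df$subject_id[i] & fold_of != fold_of[i])
  }, logical(1))
  new_fold_assignment(fold_of, K, by = "segment", seed = seed,
                      leakage_fraction = mean(leak))
}

total_variation <- function(p, q) sum(abs(p / sum(p) - q / sum(q))) / 2

#' Audit a fold assignment against the segment population
#'
#' @param assignment A `fold_assignment`.
#' @param segments The segments it refers to (list or metadata data frame).
#' @return List with per-fold SBP/DBP class histograms, joint-class
#'   frequencies, per-fold total-variation distance to the global joint
#'   distribution, segment counts and the leakage fraction.
#' @export
audit_split <- function(assignment, segments) {
  df <- if (is.data.frame(segments)) segments else segments_meta(segments)
  enc <- encode_bp_class(df$sbp, df$dbp)
  if (assignment$by == "subject") {
    unknown <- setdiff(unique(df$subject_id), names(assignment$assignment))
    if (length(unknown) > 0) {
      stop_spec("audit_split: assignment missing subjects: %s",
                paste(head(unknown, 3), collapse = ", "))
    }
    fold_of_seg <- assignment$assignment[df$subject_id]
  } else {
    if (length(assignment$assignment) != nrow(df)) {
      stop_spec("audit_split: segment-keyed assignment length mismatch")
    }
    fold_of_seg <- assignment$assignment
  }
  K <- assignment$K
  joint <- t(vapply(seq_len(K), function(f) {
    tabulate(enc$joint_class[fold_of_seg == f], nbins = 16L)
  }, numeric(16)))
  sbp_h <- t(vapply(seq_len(K), function(f) {
    tabulate(enc$sbp_class[fold_of_seg == f], nbins = 4L)
  }, numeric(4)))
  dbp_h <- t(vapply(seq_len(K), function(f) {
    tabulate(enc$dbp_class[fold_of_seg == f], nbins = 4L)
  }, numeric(4)))
  global <- tabulate(enc$joint_class, nbins = 16L)
  tv <- vapply(seq_len(K), function(f) {
    if (sum(joint[f, ]) == 0) return(NA_real_)
    total_variation(joint[f, ], global)
  }, numeric(1))
  leak <- vapply(seq_len(nrow(df)), function(i) {
    any(df$subject_id == df$subject_id[i] & fold_of_seg != fold_of_seg[i])
  }, logical(1))
  list(joint_class_counts = joint, sbp_class_counts = sbp_h,
       dbp_class_counts = dbp_h, fold_sizes = rowSums(joint),
       tv_distance = tv, max_tv = max(tv, na.rm = TRUE),
       leakage_fraction = mean(leak),
       fold_of_segment = fold_of_seg)
}
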