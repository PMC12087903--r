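# Synthetic multi-subject DE-feature generator. DE features are simulated
# directly (Gaussian with structure) rather than via raw EEG: the model
# consumes DE features, so this isolates the method under test. Per subject
# s and trial of class c:
#
#   features[t] = gain_s * (mu_c + z_t) + offset_s + eps_t
#
# with z_t an AR(1) process over time whose innovations are correlated
# within channel blocks (graph structure for the adjacency to recover),
# mu_c class mean patterns separated by class_sep noise-SD units, and
# gain/offset drawn once per subject (the affine subject shift a DANN can
# reduce).

#' Simulation configuration
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_subject trials per subject; class labels cycle so
#'   classes are balanced.
#' @param L samples (seconds) per trial.
#' @param N channels.
#' @param F_de frequency bands.
#' @param C emotion classes.
#' @param class_sep distance between class mean patterns in noise-SD units.
#' @param ar_coef temporal AR(1) coefficient in `[0, 1)`.
#' @param graph_blocks list of integer vectors partitioning `1:N` into
#'   correlated channel blocks; default two equal halves.
#' @param block_corr within-block innovation correlation in `[0, 1)`.
#' @param subject_shift per-subject affine perturbation scale: length-2
#'   `(gain SD, offset SD)`, or a scalar used for both.
#' @param noise_sd SD of the structured temporal component.
#' @param eps_sd SD of additional white measurement noise (default 0 so the
#'   lag-1 autocorrelation of the features matches `ar_coef`).
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 4, n_trials_per_subject = 6, L = 12,
                       N = 8, F_de = 5, C = 3, class_sep = 2, ar_coef = 0.5,
                       graph_blocks = NULL, block_corr = 0.6,
                       subject_shift = 0, noise_sd = 1, eps_sd = 0,
                       seed = 1) {
  if (is.null(graph_blocks)) {
    graph_blocks <- split(seq_len(N), rep(1:2, length.out = N, each = ceiling(N / 2)))
  }
  members <- sort(unlist(graph_blocks))
  if (!identical(as.integer(members), seq_len(N))) {
    stop("graph_blocks must partition 1:N", call. = FALSE)
  }
  if (length(subject_shift) == 1L) subject_shift <- rep(subject_shift, 2L)
  stopifnot(ar_coef >= 0, ar_coef < 1, block_corr >= 0, block_corr < 1,
            class_sep >= 0, noise_sd >= 0, eps_sd >= 0,
            all(subject_shift >= 0))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_subject = as.integer(n_trials_per_subject),
                 L = as.integer(L), N = as.integer(N),
                 F_de = as.integer(F_de), C = as.integer(C),
                 class_sep = class_sep, ar_coef = ar_coef,
                 graph_blocks = lapply(graph_blocks, as.integer),
                 block_corr = block_corr, subject_shift = subject_shift,
                 noise_sd = noise_sd, eps_sd = eps_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

block_membership <- function(cfg) {
  mem <- integer(cfg$N)
  for (b in seq_along(cfg$graph_blocks)) mem[cfg$graph_blocks[[b]]] <- b
  mem
}

# One innovation draw: N x F_de, within-block correlation block_corr.
draw_innovations <- function(cfg, membership) {
  shared <- matrix(stats::rnorm(length(cfg$graph_blocks) * cfg$F_de),
                   length(cfg$graph_blocks), cfg$F_de)
  own <- matrix(stats::rnorm(cfg$N * cfg$F_de), cfg$N, cfg$F_de)
  cfg$noise_sd * (sqrt(cfg$block_corr) * shared[membership, , drop = FALSE] +
                    sqrt(1 - cfg$block_corr) * own)
}

#' Generate a synthetic multi-subject DE-feature dataset
#'
#' Fully reproducible from `cfg$seed`. Returns the dataset together with
#' the ground truth used to build it (class mean patterns, channel block
#' membership, per-subject affine transforms).
#'
#' @param cfg a [sim_config()].
#' @return List with `dataset` (an [eeg_dataset()]) and `ground_truth`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  membership <- block_membership(cfg)
  # class mean patterns: random directions scaled so pairwise distances are
  # ~ class_sep * noise_sd (two independent unit vectors are ~sqrt(2) apart)
  mu <- lapply(seq_len(cfg$C), function(c) {
    m <- matrix(stats::rnorm(cfg$N * cfg$F_de), cfg$N, cfg$F_de)
    m / sqrt(sum(m^2)) * cfg$class_sep * cfg$noise_sd / sqrt(2)
  })
  transforms <- lapply(seq_len(cfg$n_subjects), function(s) {
    list(gain = 1 + matrix(stats::rnorm(cfg$N * cfg$F_de, 0, cfg$subject_shift[1]),
                           cfg$N, cfg$F_de),
         offset = matrix(stats::rnorm(cfg$N * cfg$F_de, 0, cfg$subject_shift[2]),
                         cfg$N, cfg$F_de))
  })
  trials <- list()
  for (s in seq_len(cfg$n_subjects)) {
    tf <- transforms[[s]]
    for (tr in seq_len(cfg$n_trials_per_subject)) {
      cls <- (tr - 1L) %% cfg$C
      z <- draw_innovations(cfg, membership)          # stationary start
      feats <- array(0, dim = c(cfg$L, cfg$N, cfg$F_de))
      for (t in seq_len(cfg$L)) {
        if (t > 1L) {
          z <- cfg$ar_coef * z +
            sqrt(1 - cfg$ar_coef^2) * draw_innovations(cfg, membership)
        }
        x <- tf$gain * (mu[[cls + 1L]] + z) + tf$offset
        if (cfg$eps_sd > 0) {
          x <- x + matrix(stats::rnorm(cfg$N * cfg$F_de, 0, cfg$eps_sd),
                          cfg$N, cfg$F_de)
        }
        feats[t, , ] <- x
      }
      trials[[length(trials) + 1L]] <-
        trial_features(feats, label = cls, subject_id = sprintf("S%02d", s))
    }
  }
  dataset <- eeg_dataset(trials, class_names = paste0("class", seq_len(cfg$C) - 1L))
  list(dataset = dataset,
       ground_truth = list(class_means = mu, block_membership = membership,
                           subject_transforms = transforms, config = cfg))
}

#' Ground-truth block affinity matrix
#'
#' Binary `N x N` matrix: 1 for pairs of channels in the same block, 0
#' otherwise, zero diagonal. Target for the adjacency-recovery check.
#'
#' @param membership integer vector of block ids per channel.
#' @return Binary `N x N` matrix.
#' @export
ground_truth_affinity <- function(membership) {
  A <- outer(membership, membership, `==`) * 1
  diag(A) <- 0
  A
}

#' Named synthetic presets used by the test suite
#'
#' \describe{
#'   \item{`tiny_within`}{1 subject, 15 trials, `L = 30`, `N = 8`,
#'     `F_de = 5`, 3 classes, clearly separable (`class_sep = 3`), no
#'     subject shift.}
#'   \item{`tiny_cross`}{4 subjects, 6 trials each, `L = 12`, no subject
#'     shift (null control for the domain-adaptation ablation).}
#'   \item{`shifted_cross`}{as `tiny_cross` but with `subject_shift = 0.5`
#'     (gain and offset SD), so domain alignment has shift to remove.}
#' }
#'
#' @param kind preset name.
#' @param seed RNG seed.
#' @return List with `dataset` and `ground_truth` (see [generate_dataset()]).
#' @export
make_fixture <- function(kind = c("tiny_within", "tiny_cross", "shifted_cross"),
                         seed = 1) {
  kind <- match.arg(kind)
  cfg <- switch(kind,
    tiny_within = sim_config(n_subjects = 1, n_trials_per_subject = 15,
                             L = 30, N = 8, F_de = 5, C = 3, class_sep = 3,
                             ar_coef = 0.5, block_corr = 0.6,
                             subject_shift = 0, noise_sd = 1, seed = seed),
    tiny_cross = sim_config(n_subjects = 4, n_trials_per_subject = 6,
                            L = 12, N = 8, F_de = 5, C = 3, class_sep = 2,
                            ar_coef = 0.5, block_corr = 0.6,
                            subject_shift = 0, noise_sd = 1, seed = seed),
    shifted_cross = sim_config(n_subjects = 4, n_trials_per_subject = 6,
                               L = 12, N = 8, F_de = 5, C = 3, class_sep = 2,
                               ar_coef = 0.5, block_corr = 0.6,
                               subject_shift = 0.5, noise_sd = 1,
                               seed = seed))
  generate_dataset(cfg)
}
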