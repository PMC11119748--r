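# Synthetic cohort generator. Emulates the statistical structure of a
# head-and-neck-cancer passage-reading corpus with known ground truth:
# coupled intelligibility/severity scores on [0, 10], embeddings carrying
# those scores along two fixed orthogonal signal directions plus speaker
# nuisance and isotropic noise, and judge panels with subject, judge-bias
# and error variance components.

#' Cohort specification
#'
#' @param n_speakers number of speakers (at least 2).
#' @param severity_distribution function(n) drawing severity scores with
#'   support [0, 10]; default uniform, which maximizes rank-metric
#'   testability.
#' @param int_sev_coupling_sd sd (score units) of the Gaussian perturbation
#'   coupling intelligibility to severity; 0 makes the scores identical.
#' @param embedding_dim embedding dimension (must match the regressor).
#' @param signal_directions_seed seed fixing the two orthonormal signal
#'   directions (and nuisance directions), independent of the cohort seed.
#' @param nuisance_dim number of speaker-nuisance directions (strictly less
#'   than \code{embedding_dim - 2}).
#' @param noise_sd per-coordinate sd of the isotropic embedding noise.
#' @param judges list with \code{k} (panel size), \code{bias_sd} (judge bias
#'   sd) and \code{error_sd} (residual rating error sd), all score units.
#' @param seed global cohort seed.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_speakers = 200L,
                        severity_distribution = function(n) stats::runif(n, 0, 10),
                        int_sev_coupling_sd = 1,
                        embedding_dim = 512L,
                        signal_directions_seed = 2024L,
                        nuisance_dim = 8L,
                        noise_sd = 0.5,
                        judges = list(k = 6L, bias_sd = 1, error_sd = 1),
                        seed = 1L) {
  ps_validate(n_speakers >= 2L, "n_speakers must be at least 2")
  ps_validate(int_sev_coupling_sd >= 0 && noise_sd >= 0 &&
                judges$bias_sd >= 0 && judges$error_sd >= 0,
              "standard deviations must be non-negative")
  ps_validate(judges$k >= 2L, "judge panel needs at least 2 judges")
  if (nuisance_dim >= embedding_dim - 1L) {
    ps_stop("nuisance_dim must be smaller than embedding_dim - 2",
            "ps_validation_error")
  }
  structure(list(n_speakers = as.integer(n_speakers),
                 severity_distribution = severity_distribution,
                 int_sev_coupling_sd = int_sev_coupling_sd,
                 embedding_dim = as.integer(embedding_dim),
                 signal_directions_seed = as.integer(signal_directions_seed),
                 nuisance_dim = as.integer(nuisance_dim),
                 noise_sd = noise_sd, judges = judges,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# fixed orthonormal directions: u1 (INT), u2 (SEV), then nuisance columns
signal_directions <- function(spec) {
  with_seed(spec$signal_directions_seed, {
    m <- matrix(stats::rnorm(spec$embedding_dim * (2L + spec$nuisance_dim)),
                spec$embedding_dim)
    qr.Q(qr(m))
  })
}

#' Sample a synthetic cohort
#'
#' Draws SEV from the severity distribution, sets
#' \code{INT = clamp(SEV + N(0, coupling_sd), 0, 10)}, builds embeddings as
#' \code{u1 INT + u2 SEV + nuisance + N(0, noise_sd)} with fixed orthonormal
#' unit directions, and simulates per-judge ratings
#' \code{clamp(true + bias_j + error_ij, 0, 10)} for both measures. Fully
#' reproducible per seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return object of class \code{speech_cohort}: \code{speakers}
#'   (data.frame id, int, sev), \code{embeddings} (n x dim),
#'   \code{ratings_int}, \code{ratings_sev} (\code{ratings_matrix}), and the
#'   \code{spec}.
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  U <- signal_directions(spec)
  u1 <- U[, 1L]; u2 <- U[, 2L]
  Un <- if (spec$nuisance_dim > 0L) U[, -(1:2), drop = FALSE] else NULL

  with_seed(spec$seed, {
    n <- spec$n_speakers
    sev <- clamp01_10(spec$severity_distribution(n))
    int <- clamp01_10(sev + stats::rnorm(n, 0, spec$int_sev_coupling_sd))
    emb <- outer(int, u1) + outer(sev, u2)
    if (!is.null(Un)) {
      emb <- emb + matrix(stats::rnorm(n * spec$nuisance_dim), n) %*% t(Un)
    }
    if (spec$noise_sd > 0) {
      emb <- emb + matrix(stats::rnorm(n * spec$embedding_dim, 0,
                                       spec$noise_sd), n)
    }
    ids <- sprintf("SPK%04d", seq_len(n))
    rownames(emb) <- ids

    k <- spec$judges$k
    panel <- function(true) {
      b <- stats::rnorm(k, 0, spec$judges$bias_sd)
      e <- matrix(stats::rnorm(n * k, 0, spec$judges$error_sd), n)
      ratings_matrix(clamp01_10(outer(true, rep(1, k)) +
                                  outer(rep(1, n), b) + e),
                     subjects = ids, judges = sprintf("J%d", seq_len(k)))
    }
    structure(list(spec = spec,
                   speakers = data.frame(id = ids, int = int, sev = sev,
                                         stringsAsFactors = FALSE),
                   embeddings = emb,
                   ratings_int = panel(int),
                   ratings_sev = panel(sev)),
              class = "speech_cohort")
  })
}

#' @export
print.speech_cohort <- function(x, ...) {
  cat(sprintf(
    "<speech_cohort> %d speakers, %d-dim embeddings, %d judges (seed %d)\n",
    nrow(x$speakers), ncol(x$embeddings), x$spec$judges$k, x$spec$seed))
  invisible(x)
}

#' Synthesize toy passage audio for one speaker
#'
#' Builds a 16 kHz waveform of eight voiced bursts separated by silences
#' longer than the default pause-detector minimum, so the default
#' segmentation always yields eight segments. The harmonic-to-noise mix
#' degrades as severity decreases: a severity-0 speaker is mostly aperiodic
#' (higher spectral flatness), a severity-10 speaker is cleanly harmonic.
#'
#' @param speaker one row of a cohort's \code{speakers} table (or any list
#'   with \code{id}, \code{sev}).
#' @param seed integer seed (deterministic output).
#' @param sample_rate output rate, default 16000.
#' @param burst_s,gap_s burst and silence durations in seconds.
#' @return a \code{waveform}.
#' @export
synth_passage_audio <- function(speaker, seed = 1L, sample_rate = 16000L,
                                burst_s = 0.35, gap_s = 0.32) {
  sev <- as.numeric(speaker$sev)
  ps_validate(is.finite(sev) && sev >= 0 && sev <= 10,
              "speaker severity must lie in [0, 10]")
  with_seed(seed, {
    f0 <- stats::runif(1, 95, 135)                     # per-speaker pitch
    nb <- round(burst_s * sample_rate)
    ng <- round(gap_s * sample_rate)
    t <- (seq_len(nb) - 1L) / sample_rate
    ramp <- pmin(1, pmin(seq_len(nb), rev(seq_len(nb))) / (0.01 * sample_rate))
    w_noise <- 0.1 + 0.8 * (10 - sev) / 10             # degrades with severity
    bursts <- lapply(seq_len(8L), function(b) {
      harm <- Reduce(`+`, lapply(1:8, function(h) sin(2 * pi * h * f0 * t) / h))
      harm <- harm / max(abs(harm))
      noise <- stats::rnorm(nb)
      noise <- noise / max(abs(noise))
      s <- ((1 - w_noise) * harm + w_noise * noise) * ramp
      0.9 * s / max(abs(s))
    })
    gap <- numeric(ng)
    x <- numeric(0)
    for (b in seq_len(8L)) {
      x <- c(x, bursts[[b]])
      if (b < 8L) x <- c(x, gap)
    }
    waveform(x, sample_rate)
  })
}

#' Convert a cohort to a training set
#'
#' One labeled example per speaker: the embedding with the true score pair
#' as target and the speaker id as provenance.
#'
#' @param cohort a \code{speech_cohort}.
#' @return list of class \code{training_set} with \code{embeddings},
#'   \code{targets} (data.frame int, sev) and \code{provenance}
#'   (data.frame speaker_id, segment_index, augmentation_factor).
#' @export
cohort_to_training_table <- function(cohort) {
  stopifnot(inherits(cohort, "speech_cohort"))
  structure(list(
    embeddings = cohort$embeddings,
    targets = cohort$speakers[, c("int", "sev")],
    provenance = data.frame(speaker_id = cohort$speakers$id,
                            segment_index = NA_integer_,
                            augmentation_factor = NA_real_,
                            stringsAsFactors = FALSE)
  ), class = "training_set")
}

#' Write a cohort to a directory of plain-text tables
#'
#' Writes \code{speakers.tsv} (id, int, sev), \code{embeddings.tsv} and the
#' two ratings matrices; the reverse of \code{\link{read_cohort_dir}}.
#'
#' @param cohort a \code{speech_cohort}.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$speakers, file.path(dir, "speakers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = rownames(cohort$embeddings),
                                format(cohort$embeddings, digits = 17),
                                check.names = FALSE),
                     file.path(dir, "embeddings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_ratings_tsv(cohort$ratings_int, file.path(dir, "ratings_int.tsv"))
  write_ratings_tsv(cohort$ratings_sev, file.path(dir, "ratings_sev.tsv"))
  invisible(dir)
}

#' @rdname write_cohort_dir
#' @param dir directory written by \code{write_cohort_dir}.
#' @return \code{read_cohort_dir}: list with \code{speakers},
#'   \code{embeddings}, \code{ratings_int}, \code{ratings_sev}.
#' @export
read_cohort_dir <- function(dir) {
  speakers <- utils::read.table(file.path(dir, "speakers.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  edf <- utils::read.table(file.path(dir, "embeddings.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  emb <- as.matrix(edf[, -1L, drop = FALSE])
  rownames(emb) <- edf$id
  list(speakers = speakers, embeddings = emb,
       ratings_int = read_ratings_tsv(file.path(dir, "ratings_int.tsv")),
       ratings_sev = read_ratings_tsv(file.path(dir, "ratings_sev.tsv")))
}
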