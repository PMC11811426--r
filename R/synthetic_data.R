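# Synthetic multimodal corpus generator.
#
# The generator emulates the statistical structure the diagnostic method
# assumes in real interview data: depressed speakers (label 1) speak with a
# lower and less variable fundamental frequency ("monotonous and lower
# tone"), and show reduced facial dynamics, here a moving 2-D Gaussian blob
# whose oscillation amplitude and frequency shrink with the label. The PHQ-8
# score is coupled to the binary label through the threshold rule
# (label 1 iff PHQ-8 > positive_threshold, default 10).

#' Configuration for the synthetic corpus generator
#'
#' @param n_subjects Number of subjects.
#' @param prevalence Fraction of label-1 (depressed) subjects; the generated
#'   corpus contains exactly `round(prevalence * n_subjects)` positives.
#' @param effect_size Nonnegative separation between the class-conditional
#'   signal distributions; 0 means the labels carry no signal.
#' @param effect_size_audio,effect_size_video Optional per-modality overrides
#'   of `effect_size` (used to construct corpora where each modality carries
#'   an independent share of the signal).
#' @param frames_per_clip Frames in each video clip.
#' @param frame_size Integer `(height, width)` of a frame; at least 8x8.
#' @param sample_rate Audio sampling rate in Hz.
#' @param clip_seconds Audio duration per subject in seconds.
#' @param split Proportions for train/validation/test. The default mirrors a
#'   163/56/10 partition.
#' @param positive_threshold PHQ-8 cutoff: label 1 iff score strictly exceeds
#'   this value.
#' @param seed Integer seed; together with the other fields it fully
#'   determines the corpus (same config, byte-identical files).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 200, prevalence = 0.5,
                             effect_size = 1,
                             effect_size_audio = NULL,
                             effect_size_video = NULL,
                             frames_per_clip = 8, frame_size = c(32, 32),
                             sample_rate = 16000, clip_seconds = 2,
                             split = c(train = 163, val = 56, test = 10) / 229,
                             positive_threshold = 10, seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be positive")
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must be in (0, 1]")
  if (effect_size < 0) stop("effect_size must be nonnegative")
  if (clip_seconds <= 0) stop("clip_seconds must be positive")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (frames_per_clip < 1) stop("frames_per_clip must be positive")
  if (any(frame_size < 8)) stop("frame_size must be at least 8x8")
  if (abs(sum(split) - 1) > 1e-8) stop("split proportions must sum to 1")
  structure(list(
    n_subjects = as.integer(n_subjects), prevalence = prevalence,
    effect_size = effect_size,
    effect_size_audio = if (is.null(effect_size_audio)) effect_size else effect_size_audio,
    effect_size_video = if (is.null(effect_size_video)) effect_size else effect_size_video,
    frames_per_clip = as.integer(frames_per_clip),
    frame_size = as.integer(frame_size),
    sample_rate = as.integer(sample_rate), clip_seconds = clip_seconds,
    split = split, positive_threshold = as.integer(positive_threshold),
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Subject-level metadata table. Labels are assigned by permutation so the
# positive count is exact; PHQ-8 is drawn uniformly on the side of the
# threshold the label dictates; sex is Bernoulli(0.5).
generate_records <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_local_seed(derive_seed(cfg$seed, 0L, 1L), {
    n <- cfg$n_subjects
    n_pos <- round(cfg$prevalence * n)
    label <- integer(n)
    label[sample.int(n, n_pos)] <- 1L
    thr <- cfg$positive_threshold
    phq8 <- integer(n)
    phq8[label == 1L] <- sample((thr + 1L):24L, sum(label == 1L), replace = TRUE)
    phq8[label == 0L] <- sample(0L:thr, sum(label == 0L), replace = TRUE)
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      label = label,
      phq8 = phq8,
      sex = sample(c("male", "female"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

subject_index <- function(record) {
  as.integer(sub("^S", "", record$subject_id))
}

#' Generate one subject's audio clip
#'
#' The waveform is a harmonic complex (fundamental plus two harmonics) whose
#' instantaneous pitch follows a discretised Ornstein-Uhlenbeck process.
#' Label-1 subjects receive a lower mean fundamental and a smaller
#' stationary pitch standard deviation, both gaps scaled by
#' `effect_size_audio`; at effect size 0 the two class-conditional
#' distributions coincide. Additive Gaussian noise is applied throughout.
#'
#' @param record One-row data frame (or list) with at least `subject_id` and
#'   `label`.
#' @param cfg A [generator_config()].
#' @return Numeric waveform of length `sample_rate * clip_seconds` in
#'   `[-1, 1]`.
#' @export
generate_audio <- function(record, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(record$label)) stop("record$label must be set")
  e <- cfg$effect_size_audio
  lab <- as.numeric(record$label)
  n <- as.integer(round(cfg$sample_rate * cfg$clip_seconds))
  if (n < 1) stop("non-positive clip duration")
  with_local_seed(derive_seed(cfg$seed, subject_index(record), 2L), {
    f0_mean <- 165 - 12 * e * lab + stats::rnorm(1, 0, 6)
    pitch_sd <- 14 * exp(-0.35 * e * lab)
    # OU pitch track as an AR(1): x_t = phi x_{t-1} + eps, stationary sd pitch_sd
    phi <- exp(-4 / cfg$sample_rate)          # ~4 Hz mean-reversion
    innov_sd <- pitch_sd * sqrt(1 - phi^2)
    drift <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                                      method = "recursive"))
    f <- pmax(f0_mean + drift, 40)
    phase <- 2 * pi * cumsum(f) / cfg$sample_rate
    wave <- 0.6 * sin(phase) + 0.3 * sin(2 * phase) + 0.15 * sin(3 * phase)
    wave <- 0.35 * wave + stats::rnorm(n, 0, 0.02)
    pmin(pmax(wave, -1), 1)
  })
}

#' Generate one subject's video clip
#'
#' Each frame holds a 2-D Gaussian blob whose centre oscillates smoothly.
#' Label-1 subjects get a smaller oscillation amplitude and a lower
#' oscillation frequency (reduced facial dynamics), gaps scaled by
#' `effect_size_video`. Pixel values are clipped to `[0, 1]`.
#'
#' @inheritParams generate_audio
#' @return Rank-4 array `(frames, height, width, channels = 1)`.
#' @export
generate_video <- function(record, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (any(cfg$frame_size < 8)) stop("frame_size must be at least 8x8")
  e <- cfg$effect_size_video
  lab <- as.numeric(record$label)
  H <- cfg$frame_size[1]; W <- cfg$frame_size[2]; TT <- cfg$frames_per_clip
  with_local_seed(derive_seed(cfg$seed, subject_index(record), 3L), {
    amp <- 0.12 * min(H, W) * exp(-0.35 * e * lab) * exp(stats::rnorm(1, 0, 0.12))
    cyc <- 1.5 * exp(-0.15 * e * lab) * exp(stats::rnorm(1, 0, 0.08))
    sig <- 0.08 * min(H, W) * exp(stats::rnorm(1, 0, 0.1))
    cy <- H / 2 + stats::rnorm(1, 0, H / 12)
    cx <- W / 2 + stats::rnorm(1, 0, W / 12)
    ph_y <- stats::runif(1, 0, 2 * pi)
    ph_x <- stats::runif(1, 0, 2 * pi)
    clip <- array(0, dim = c(TT, H, W, 1))
    t_frac <- (seq_len(TT) - 1) / TT
    ys <- seq_len(H); xs <- seq_len(W)
    for (t in seq_len(TT)) {
      oy <- cy + amp * sin(2 * pi * cyc * t_frac[t] + ph_y)
      ox <- cx + amp * sin(2 * pi * cyc * t_frac[t] + ph_x)
      frame <- outer(exp(-(ys - oy)^2 / (2 * sig^2)),
                     exp(-(xs - ox)^2 / (2 * sig^2)))
      clip[t, , , 1] <- frame
    }
    clip <- clip + stats::rnorm(length(clip), 0, 0.02)
    pmin(pmax(clip, 0), 1)
  })
}

# Largest-remainder allocation of n into proportions p (within +-1 of exact).
allocate_split <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Label-stratified split assignment, deterministic given the config seed.
# Global split sizes are fixed first (largest remainder, so each is within
# one of proportional); strata are then filled against those quotas.
assign_splits <- function(records, cfg) {
  with_local_seed(derive_seed(cfg$seed, 0L, 4L), {
    n <- nrow(records)
    remaining <- allocate_split(n, cfg$split)
    labs <- unique(records$label)
    split <- character(n)
    for (k in seq_along(labs)) {
      idx <- sample(which(records$label == labs[k]))
      if (k == length(labs)) {
        sizes <- remaining
      } else {
        sizes <- pmin(allocate_split(length(idx), cfg$split), remaining)
        deficit <- length(idx) - sum(sizes)
        while (deficit > 0) {
          j <- which.max(remaining - sizes)
          sizes[j] <- sizes[j] + 1L
          deficit <- deficit - 1L
        }
      }
      split[idx] <- rep(names(cfg$split), times = sizes)
      remaining <- remaining - sizes
    }
    split
  })
}

#' Generate and write a complete synthetic corpus
#'
#' Writes one 16-bit PCM WAV per subject, one RDS array container per clip
#' (a list with the named array `frames`), and a comma-delimited manifest
#' with columns `subject_id,label,phq8,sex,audio_path,video_path,split`.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Refuse to clobber an existing manifest unless `TRUE`.
#' @return The manifest data frame, invisibly annotated with `out_dir`.
#' @export
generate_corpus <- function(cfg, out_dir, overwrite = FALSE) {
  stopifnot(inherits(cfg, "generator_config"))
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists at ", manifest_path,
         "; use overwrite = TRUE to regenerate")
  }
  dir.create(file.path(out_dir, "audio"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "video"), recursive = TRUE, showWarnings = FALSE)
  records <- generate_records(cfg)
  records$audio_path <- file.path("audio", paste0(records$subject_id, ".wav"))
  records$video_path <- file.path("video", paste0(records$subject_id, ".rds"))
  records$split <- assign_splits(records, cfg)
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    write_wav(generate_audio(rec, cfg), file.path(out_dir, rec$audio_path),
              cfg$sample_rate)
    saveRDS(list(frames = generate_video(rec, cfg)),
            file.path(out_dir, rec$video_path), compress = "gzip")
  }
  utils::write.csv(records, manifest_path, row.names = FALSE, quote = FALSE)
  attr(records, "out_dir") <- out_dir
  invisible(records)
}

#' Read a corpus manifest written by [generate_corpus()]
#'
#' @param out_dir Corpus directory containing `manifest.csv`.
#' @return The manifest data frame with attribute `out_dir`.
#' @export
read_manifest <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("no manifest at ", manifest_path)
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  attr(m, "out_dir") <- out_dir
  m
}

#' Load a clip written by [generate_corpus()]
#'
#' @param path Path to the RDS array container.
#' @return Rank-4 array `(frames, height, width, channels)`.
#' @export
load_clip <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$frames)) stop("clip container has no 'frames' array: ", path)
  obj$frames
}
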