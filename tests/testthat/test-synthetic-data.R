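test_that("generator config validates its inputs", {
  expect_error(generator_config(clip_seconds = 0), "clip_seconds")
  expect_error(generator_config(sample_rate = -1), "sample_rate")
  expect_error(generator_config(frame_size = c(4, 32)), "frame_size")
  expect_error(generator_config(prevalence = 0), "prevalence")
  expect_error(generator_config(effect_size = -1), "effect_size")
})

test_that("labels follow the PHQ-8 threshold rule with exact prevalence", {
  cfg <- generator_config(n_subjects = 10, prevalence = 0.5, seed = 3)
  rec <- mmdepnet:::generate_records(cfg)
  expect_equal(nrow(rec), 10)
  expect_equal(sum(rec$label == 1), 5)
  expect_true(all(rec$phq8 >= 0 & rec$phq8 <= 24))
  expect_equal(rec$label == 1, rec$phq8 > 10)

  cfg_all <- generator_config(n_subjects = 20, prevalence = 1.0, seed = 4)
  rec_all <- mmdepnet:::generate_records(cfg_all)
  expect_true(all(rec_all$phq8 > 10))

  # configurable binarisation boundary: score 10 itself is negative
  cfg2 <- generator_config(n_subjects = 50, prevalence = 0.5,
                           positive_threshold = 10, seed = 5)
  rec2 <- mmdepnet:::generate_records(cfg2)
  expect_false(any(rec2$phq8 == 10 & rec2$label == 1))
})

test_that("train/val/test allocation stays within one of proportionality", {
  cfg <- generator_config(n_subjects = 229, seed = 6)
  rec <- mmdepnet:::generate_records(cfg)
  split <- mmdepnet:::assign_splits(rec, cfg)
  expect_equal(unname(table(split)[c("train", "val", "test")]),
               c(163L, 56L, 10L), ignore_attr = TRUE)

  cfg2 <- generator_config(n_subjects = 200, seed = 7)
  rec2 <- mmdepnet:::generate_records(cfg2)
  split2 <- mmdepnet:::assign_splits(rec2, cfg2)
  expected <- 200 * cfg2$split
  got <- table(split2)[names(cfg2$split)]
  expect_true(all(abs(got - expected) <= 1 + 1e-9))
})

test_that("identical configs give identical signals and byte-identical corpora", {
  cfg <- generator_config(n_subjects = 3, frames_per_clip = 4,
                          clip_seconds = 0.25, seed = 12)
  rec <- mmdepnet:::generate_records(cfg)
  expect_identical(generate_audio(rec[1, ], cfg), generate_audio(rec[1, ], cfg))
  expect_identical(generate_video(rec[2, ], cfg), generate_video(rec[2, ], cfg))

  d1 <- file.path(tempdir(), "mmdep-det1")
  d2 <- file.path(tempdir(), "mmdep-det2")
  generate_corpus(cfg, d1, overwrite = TRUE)
  generate_corpus(cfg, d2, overwrite = TRUE)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6))
  }
})

test_that("an existing manifest is not overwritten silently", {
  cfg <- generator_config(n_subjects = 2, frames_per_clip = 4,
                          clip_seconds = 0.25, seed = 13)
  d <- file.path(tempdir(), "mmdep-ovw")
  generate_corpus(cfg, d, overwrite = TRUE)
  expect_error(generate_corpus(cfg, d), "overwrite")
})

test_that("zero effect size removes the class signal from both modalities", {
  cfg <- generator_config(n_subjects = 60, effect_size = 0,
                          clip_seconds = 0.5, frames_per_clip = 6, seed = 14)
  rec <- mmdepnet:::generate_records(cfg)
  pitch <- vapply(seq_len(60), function(i)
    oracle_pitch(generate_audio(rec[i, ], cfg), cfg$sample_rate), numeric(1))
  expect_gt(t.test(pitch[rec$label == 1], pitch[rec$label == 0])$p.value, 0.01)
  motion <- vapply(seq_len(60), function(i)
    clip_motion(generate_video(rec[i, ], cfg)), numeric(1))
  expect_gt(t.test(motion[rec$label == 1], motion[rec$label == 0])$p.value, 0.01)
})

test_that("effect size three separates the classes in both modalities", {
  cfg <- generator_config(n_subjects = 60, effect_size = 3,
                          clip_seconds = 0.5, frames_per_clip = 6, seed = 15)
  rec <- mmdepnet:::generate_records(cfg)
  pitch <- vapply(seq_len(60), function(i)
    oracle_pitch(generate_audio(rec[i, ], cfg), cfg$sample_rate), numeric(1))
  tt <- t.test(pitch[rec$label == 1], pitch[rec$label == 0])
  expect_lt(tt$p.value, 0.01)
  expect_lt(mean(pitch[rec$label == 1]), mean(pitch[rec$label == 0]))
  expect_lt(stats::sd(pitch[rec$label == 1]), stats::sd(pitch[rec$label == 0]))
  motion <- vapply(seq_len(60), function(i)
    clip_motion(generate_video(rec[i, ], cfg)), numeric(1))
  expect_gt(oracle_threshold_acc(motion, rec$label), 0.9)
})

test_that("oracle separability is non-decreasing in effect size", {
  aucs <- vapply(0:3, function(e) {
    cfg <- generator_config(n_subjects = 60, effect_size = e,
                            clip_seconds = 0.4, frames_per_clip = 6,
                            seed = 16)
    rec <- mmdepnet:::generate_records(cfg)
    motion <- vapply(seq_len(60), function(i)
      clip_motion(generate_video(rec[i, ], cfg)), numeric(1))
    roc_curve(-motion, rec$label)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.08))
  expect_gt(aucs[4], aucs[1])
})

test_that("WAV files round-trip within quantisation error", {
  x <- sin(2 * pi * 440 * (0:3999) / 16000) * 0.8
  p <- file.path(tempdir(), "rt.wav")
  write_wav(x, p, 16000)
  r <- read_wav(p)
  expect_equal(r$sample_rate, 16000)
  expect_equal(length(r$samples), length(x))
  expect_lt(max(abs(r$samples - x)), 1 / 32767 + 1e-9)
})

test_that("manifest and clip containers reload cleanly", {
  fx <- tiny_corpus()
  man <- read_manifest(attr(fx$manifest, "out_dir"))
  expect_equal(names(man), c("subject_id", "label", "phq8", "sex",
                             "audio_path", "video_path", "split"))
  clip <- load_clip(file.path(attr(man, "out_dir"), man$video_path[1]))
  expect_equal(dim(clip), c(4, 32, 32, 1))
  expect_true(all(clip >= 0 & clip <= 1))
})
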