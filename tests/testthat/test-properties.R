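test_that("built-in scales are complete and ordered as chemistry demands", {
  for (nm in c("H", "F", "E", "I")) {
    sc <- load_scale(nm)
    expect_length(unclass(sc), 20L)
    expect_true(all(is.finite(unclass(sc))))
  }
  h <- load_scale("H")
  expect_gt(h[["I"]], h[["R"]])  # Ile more hydrophobic than Arg
})

test_that("scale loading rejects incomplete or duplicated tables", {
  aa19 <- setdiff(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                    "K", "M", "F", "P", "S", "T", "W", "Y", "V"), "W")
  p <- tempfile()
  writeLines(paste(aa19, 1, sep = "\t"), p)
  expect_error(load_scale(p), "W")
  p2 <- tempfile()
  writeLines(paste(c(aa19, "W", "W"), 1, sep = "\t"), p2)
  expect_error(load_scale(p2), "duplicate")
  expect_error(load_scale("no_such_scale"), "neither")
})

test_that("nonstandard letters take the scale mean, with a warning", {
  sc <- toy_scale(c(A = 2), default = 0)
  expect_warning(v <- scale_values("AXA", sc), "X")
  expect_equal(v[2], mean(unclass(sc)))
})

test_that("profiles reduce to raw values at window 1 and flatten constants", {
  sc <- toy_scale(c(K = 3.7, A = 1.1, R = -2), default = 0)
  p1 <- compute_profile("KARKA", sc, window = 1)
  expect_equal(p1$values, scale_values("KARKA", sc))
  pk <- compute_profile("KKKK", sc, window = 3)
  expect_equal(pk$values, rep(3.7, 4))
})

test_that("end-truncated window means match the hand-derived example and a
           brute-force oracle", {
  sc <- toy_scale(c(A = 1, R = 2, N = 4))
  p <- compute_profile("ARN", sc, window = 3)
  expect_equal(p$values, c(1.5, 7 / 3, 3.0))
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    s <- paste(sample(c("A", "R", "N", "D", "K"), n, TRUE), collapse = "")
    w <- sample(c(1, 3, 5, 9), 1)
    w <- min(w, n - (1 - n %% 2))
    if (w %% 2 == 0) w <- w - 1
    p <- compute_profile(s, sc, window = w)
    expect_equal(p$values, brute_window_mean(scale_values(s, sc), w))
  }
})

test_that("profile smoothing is linear, bounded by raw extremes, and
           variance-reducing in the window", {
  set.seed(21)
  sc <- load_scale("H")
  for (rep in 1:100) {
    s <- paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                      40, TRUE), collapse = "")
    raw <- scale_values(s, sc)
    p9 <- compute_profile(s, sc, window = 9)$values
    # linearity: profile(a*scale + b) == a*profile + b
    sc2 <- toy_scale(stats::setNames(2 * unclass(sc) + 5, names(unclass(sc))))
    p9b <- compute_profile(s, sc2, window = 9)$values
    expect_equal(p9b, 2 * p9 + 5, tolerance = 1e-12)
    expect_true(all(p9 >= min(raw) - 1e-12 & p9 <= max(raw) + 1e-12))
    vars <- vapply(c(1, 5, 9, 15), function(w)
      stats::var(compute_profile(s, sc, window = w)$values), 0)
    expect_true(all(diff(vars) <= 1e-12))
  }
})

test_that("profile rejects even windows and windows beyond the sequence", {
  sc <- load_scale("H")
  expect_error(compute_profile("ARN", sc, window = 2), "odd")
  expect_error(compute_profile("ARN", sc, window = 5), "exceeds")
})

test_that("alignment mapping places values at columns and round-trips", {
  sc <- toy_scale(c(A = 1, C = 3))
  p <- compute_profile("AC", sc, window = 1, sequence_id = "s1")
  aps <- map_profiles_to_alignment(list(p), c(s1 = "A-C"))
  row <- aps$profiles[[p$scale_name]]["s1", ]
  expect_equal(row, c(1, NA, 3))
  expect_equal(aps$column_map$s1, c(0L, NA, 1L))

  # random alignments round-trip exactly
  set.seed(31)
  h <- load_scale("H")
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    seqs <- replicate(3, paste(sample(c("A", "R", "N", "D"), n, TRUE),
                               collapse = ""))
    rows <- vapply(seqs, function(s) {
      chars <- strsplit(s, "")[[1]]
      gaps <- sort(sample(n + 5, 5))
      out <- character(n + 5)
      out[gaps] <- "-"
      out[-gaps] <- chars
      paste(out, collapse = "")
    }, "")
    names(rows) <- paste0("r", 1:3)
    profs <- lapply(1:3, function(i)
      compute_profile(seqs[i], h, 5, paste0("r", i)))
    aps <- map_profiles_to_alignment(profs, rows)
    for (i in 1:3) {
      placed <- aps$profiles$H[paste0("r", i), ]
      expect_equal(placed[!is.na(placed)], profs[[i]]$values,
                   ignore_attr = TRUE)
    }
  }
})

test_that("alignment mapping reports the first mismatching position", {
  sc <- toy_scale(c(A = 1))
  p <- compute_profile("AAC", sc, 1, "s1")
  expect_error(map_profiles_to_alignment(list(p), c(s1 = "AA-G")),
               "position 2")
})

test_that("average pairwise identity matches brute force and handles
           degenerate pairs", {
  expect_equal(average_pairwise_identity(c(a = "ARND", b = "ARND")), 1.0)
  expect_equal(average_pairwise_identity(c(a = "AAAA", b = "CCCC")), 0.0)
  aln <- c(a = "AR-ND", b = "ARKND", c = "A--ND")
  expect_equal(average_pairwise_identity(aln), brute_identity(aln))
  set.seed(41)
  for (rep in 1:10) {
    rows <- replicate(4, paste(sample(c("A", "R", "N", "-"), 12, TRUE),
                               collapse = ""))
    names(rows) <- paste0("r", 1:4)
    if (any(vapply(rows, function(r) !grepl("[^-]", r), TRUE))) next
    expect_equal(suppressWarnings(average_pairwise_identity(rows)),
                 brute_identity(rows))
  }
  gappy <- c(a = "----", b = "AR-N", c = "ARKN")
  expect_warning(v <- average_pairwise_identity(gappy), "excluded")
  expect_equal(v, brute_identity(gappy))
})

test_that("Stockholm and aligned-FASTA readers agree and normalize gaps", {
  sto <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID test", "s1 AR.ND", "s2 ARKN-",
               "", "s1 QQ", "s2 QQ", "//"), sto)
  rows <- read_alignment(sto)
  expect_equal(rows, c(s1 = "AR-NDQQ", s2 = "ARKN-QQ"))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "AR.ND", "QQ", ">s2", "ARKN-QQ"), fa)
  expect_equal(read_alignment(fa), rows)
})
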