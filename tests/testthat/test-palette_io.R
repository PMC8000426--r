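# Loading WCS-format tables, palette construction, and CSV round trips.

write_chip_table <- function(df, path, header = FALSE) {
  lines <- apply(df, 1, paste, collapse = "\t")
  if (header) lines <- c("#cnum\tV\tH\tL\ta\tb", lines)
  writeLines(lines, path)
}

test_that("chip coordinate tables load into palettes with correct distances", {
  tf <- withr::local_tempfile(fileext = ".txt")
  write_chip_table(data.frame(id = 1:2, row = c("A", "B"), col = 0:1,
                              L = c(0, 0), a = c(0, 3), b = c(0, 4)),
                   tf, header = TRUE)
  pal <- load_wcs_palette(tf, expected_chips = 2)
  expect_equal(n_chips(pal), 2L)
  expect_equal(pal$dist[1, 2], 5)  # 3-4-5 triangle
  expect_equal(pal$prior, c(0.5, 0.5))

  # 4-chip table: distance matrix equals brute-force double loop
  coords <- matrix(c(1, 2, 3, 10, -4, 2, 0, 0, 7, 3, 3, 3), 4, 3, byrow = TRUE)
  tf2 <- withr::local_tempfile(fileext = ".txt")
  write_chip_table(data.frame(1:4, LETTERS[1:4], 1:4, coords[, 1],
                              coords[, 2], coords[, 3]), tf2)
  pal4 <- load_wcs_palette(tf2, expected_chips = 4)
  expect_equal(pal4$dist, dist_brute(coords), tolerance = 1e-9)
})

test_that("palette loading validates ids, coordinates and chip counts", {
  tf <- withr::local_tempfile(fileext = ".txt")
  write_chip_table(data.frame(c(1, 1), c("A", "A"), c(0, 1),
                              c(1, 2), c(3, 4), c(5, 6)), tf)
  expect_error(load_wcs_palette(tf, expected_chips = 2), "duplicate")

  tf2 <- withr::local_tempfile(fileext = ".txt")
  write_chip_table(data.frame(1:2, c("A", "B"), 0:1,
                              c("x", "1"), c(1, 2), c(3, 4)), tf2)
  expect_error(load_wcs_palette(tf2, expected_chips = 2), "non-numeric")

  tf3 <- withr::local_tempfile(fileext = ".txt")
  write_chip_table(data.frame(1:3, LETTERS[1:3], 1:3, 1:3, 1:3, 1:3), tf3)
  expect_warning(load_wcs_palette(tf3, expected_chips = 330), "expected 330")
  expect_error(load_wcs_palette(tf3, expected_chips = 330, strict = TRUE),
               "expected 330")
})

test_that("pairwise distances form a metric on random palettes", {
  for (seed in 1:3) {
    pal <- make_blob_palette(3, 5, separation = 20, sd = 5, seed = seed)
    d <- pal$dist
    expect_equal(d, t(d))
    expect_equal(diag(d), rep(0, n_chips(pal)))
    n <- n_chips(pal)
    for (i in 1:n) for (j in 1:n) {
      expect_true(all(d[i, j] <= d[i, ] + d[, j] + 1e-9))
    }
  }
})

test_that("palette and naming CSV round trips are identities", {
  pal <- toy_palette4()
  tf <- withr::local_tempfile(fileext = ".csv")
  write_palette_csv(pal, tf)
  pal2 <- read_palette_csv(tf)
  expect_equal(pal2$coords, pal$coords)
  expect_equal(pal2$dist, pal$dist)
  # idempotence of load -> write -> load
  tf2 <- withr::local_tempfile(fileext = ".csv")
  write_palette_csv(pal2, tf2)
  expect_equal(read_palette_csv(tf2)$coords, pal2$coords)

  ns <- make_synthetic_naming(pal, 3, softness = 6)
  tn <- withr::local_tempfile(fileext = ".csv")
  write_naming_csv(ns, tn, palette = pal)
  ns2 <- read_naming_csv(tn, palette = pal)
  expect_equal(ns2$enc, ns$enc, tolerance = 1e-12)

  # one-word system: 4 rows, probability 1
  one <- naming_system(matrix(1, 4, 1))
  tn2 <- withr::local_tempfile(fileext = ".csv")
  write_naming_csv(one, tn2)
  df <- read.csv(tn2)
  expect_equal(nrow(df), 4L)
  expect_equal(df$probability, rep(1, 4))

  # invalid row sums are rejected on read
  bad <- df
  bad$probability[1] <- 0.5
  write.csv(bad, tn2, row.names = FALSE)
  expect_error(read_naming_csv(tn2), "sum to 1")
})

write_term_table <- function(df, path) {
  writeLines(apply(df, 1, paste, collapse = "\t"), path)
}

test_that("naming data loads per language with frequency-based P(w|c)", {
  pal <- color_palette(rbind(c(0, 0, 0), c(50, 0, 0)), chip_id = 1:2)
  rows <- rbind(
    data.frame(lang = "L1", spk = paste0("s", 1:4), chip = 1,
               term = c("A", "A", "A", "B")),
    data.frame(lang = "L1", spk = paste0("s", 1:4), chip = 2, term = "B")
  )
  tf <- withr::local_tempfile(fileext = ".txt")
  write_term_table(rows, tf)
  out <- load_wcs_naming(tf, pal)
  expect_named(out$systems, "L1")
  ns <- out$systems$L1
  iA <- match("a", ns$words)
  expect_equal(ns$enc[1, iA], 0.75)  # 3 of 4 speakers said A
  expect_equal(rowSums(ns$enc), c(1, 1))
})

test_that("languages are excluded iff some chip has exactly one judgment", {
  pal <- color_palette(rbind(c(0, 0, 0), c(50, 0, 0), c(0, 50, 0)))
  mk <- function(n_by_chip, lang) {
    do.call(rbind, lapply(seq_along(n_by_chip), function(ci) {
      n <- n_by_chip[ci]
      if (n == 0) return(NULL)
      data.frame(lang = lang, spk = paste0("s", seq_len(n)), chip = ci,
                 term = "x")
    }))
  }
  rows <- rbind(mk(c(2, 2, 2), "keep"), mk(c(2, 1, 3), "sparse"))
  tf <- withr::local_tempfile(fileext = ".txt")
  write_term_table(rows, tf)
  out <- load_wcs_naming(tf, pal)
  expect_named(out$systems, "keep")
  expect_equal(out$exclusions$language, "sparse")
  expect_match(out$exclusions$reason, "single speaker")

  # unknown chip ids are an error
  rows2 <- mk(c(2, 2, 2), "L")
  rows2$chip[1] <- 99
  tf2 <- withr::local_tempfile(fileext = ".txt")
  write_term_table(rows2, tf2)
  expect_error(load_wcs_naming(tf2, pal), "absent")
})
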