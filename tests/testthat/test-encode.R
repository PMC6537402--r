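test_that("the factor table is a faithful transcription", {
  kf <- kidera_factors()
  expect_equal(dim(kf), c(20L, 10L))
  expect_setequal(rownames(kf), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  # the ten factors are standardized across the 20 residues by construction
  expect_true(all(abs(colMeans(kf)) < 0.02))
  expect_true(all(abs(apply(kf, 2, stats::sd) - 1) < 0.1))
})

test_that("fix_length implements the center trim/pad conventions", {
  expect_equal(fix_length(strrep("A", 17), 17)$seq, strrep("A", 17))
  expect_equal(fix_length("ABCDEFGHIJKLMNOPQRS", 17, "center")$seq,
               "ABCDEFGHILMNOPQRS")  # first 9 + last 8
  fx <- fix_length("ABCDEFGHIJKLMNO", 17, "center")
  expect_equal(fx$seq, "ABCDEFGH--IJKLMNO")  # 2 sentinels after position 8
  expect_equal(fx$pad, c(9L, 10L))
  expect_error(fix_length("ABC", 0), "target")
})

test_that("fix_length is idempotent and order-preserving under padding", {
  set.seed(7)
  for (i in 1:25) {
    len <- sample(1:25, 1)
    s <- paste(sample(rownames(kidera_factors()), len, replace = TRUE),
               collapse = "")
    for (mode in c("center", "ends")) {
      f1 <- fix_length(s, 17, mode)$seq
      expect_equal(fix_length(f1, 17, mode)$seq, f1)
      if (len <= 17) {
        expect_equal(gsub("-", "", f1), s)  # padding never loses residues
      }
      expect_equal(nchar(f1), 17L)
    }
  }
})

test_that("kidera_encode builds the 33 x 10 matrix from the factor table", {
  enc <- kidera_encode("AAAAAAAA", "CCCCCCCC", strrep("W", 17))
  expect_equal(dim(enc$values), c(33L, 10L))
  expect_length(as.vector(enc$values), 330L)
  kf <- kidera_factors()
  for (r in 1:8) expect_equal(unname(enc$values[r, ]), unname(kf["A", ]))
  for (r in 9:16) expect_equal(unname(enc$values[r, ]), unname(kf["C", ]))
  for (r in 17:33) expect_equal(unname(enc$values[r, ]), unname(kf["W", ]))
  # all-X input gives the zero matrix
  encx <- kidera_encode(strrep("X", 8), strrep("X", 8), strrep("X", 17))
  expect_true(all(encx$values == 0))
  # pad rows are zero rows
  encp <- kidera_encode("AAA", "CCC", strrep("W", 10))
  expect_true(all(encp$values[encp$pad_mask, ] == 0))
  expect_error(kidera_encode("AB[", "CC", "WWW"), "residue")
})

test_that("encoding is position-local", {
  s3 <- strrep("G", 17)
  base <- kidera_encode("AAAAAAAA", "CCCCCCCC", s3)$values
  mod3 <- sub("^G", "W", s3)
  changed <- kidera_encode("AAAAAAAA", "CCCCCCCC", mod3)$values
  diff_rows <- which(rowSums(base != changed) > 0)
  expect_equal(diff_rows, 17L)  # only CDR3 position 1
})

test_that("encode_repertoire flattens position-major", {
  r <- make_records(1, cdr1_aa = "AAAAAAAA", cdr2_aa = "CCCCCCCC",
                    cdr3_aa = strrep("W", 17))
  x <- encode_repertoire(r)
  expect_equal(dim(x), c(1L, 330L))
  kf <- kidera_factors()
  expect_equal(unname(x[1, 1:10]), unname(kf["A", ]))
  expect_equal(unname(x[1, 81:90]), unname(kf["C", ]))
})
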