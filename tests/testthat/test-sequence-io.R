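write_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_fasta parses, wraps, uppercases and validates", {
  p1 <- write_tmp(c(">p1", "MKV"), ".fasta")
  rec <- read_fasta(p1)
  expect_equal(rec$id, "p1")
  expect_equal(rec$sequence, "MKV")

  p2 <- write_tmp(c(">a desc", "mkvl", "ACDE", ">b", "KKK"), ".fasta")
  rec2 <- read_fasta(p2)
  expect_equal(rec2$id, c("a", "b"))
  expect_equal(rec2$sequence, c("MKVLACDE", "KKK"))

  p3 <- write_tmp(c(">bad", "MKXV"), ".fasta")
  expect_error(read_fasta(p3), "bad.*X")
  perm <- read_fasta(p3, strict = FALSE)
  expect_equal(perm$sequence, "MKOV")

  expect_error(read_fasta(tempfile()), "not found")
})

test_that("read_annotations normalises labels and validates rows", {
  p <- write_tmp(c("protein_id\tposition\tlabel",
                   "p1\t2\t1", "p1\t5\t-1", "p2\t9\t0"))
  ann <- read_annotations(p)
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$label, c(1L, -1L, -1L))
  expect_equal(ann$position, c(2L, 5L, 9L))

  expect_error(read_annotations(write_tmp("p1\t0\t1")), ">= 1")
  expect_error(read_annotations(write_tmp("p1\tx\t1")), "non-integer")
  expect_error(read_annotations(write_tmp("p1\t3\tmaybe")), "unknown label")
  csv <- write_tmp("p1,2,1", ".csv")
  expect_equal(read_annotations(csv, sep = ",")$position, 2L)
})

test_that("extract_window pads with O and records pad_count", {
  w <- extract_window("K", 1)
  expect_equal(w$peptide, paste0(strrep("O", 11), "K", strrep("O", 11)))
  expect_equal(w$pad_count, 22L)

  seq30 <- paste(rep("A", 30), collapse = "")
  w2 <- extract_window(seq30, 15)
  expect_equal(nchar(w2$peptide), 23L)
  expect_equal(w2$pad_count, 0L)

  w3 <- extract_window("ACDEFGHIKLMNPQRSTVWY", 9)
  expect_equal(w3$peptide, "OOOACDEFGHIKLMNPQRSTVWY")
  expect_equal(w3$center_residue, "K")
  expect_equal(w3$pad_count, 3L)

  expect_error(extract_window("ACD", 4), "out of range")
  expect_error(extract_window("ACD", 0), "out of range")
})

test_that("window invariants hold over random proteins and positions", {
  withr::with_seed(42, {
    for (rep in 1:50) {
      len <- sample(1:60, 1)
      seqv <- paste(sample(aa_alphabet()[1:20], len, replace = TRUE),
                    collapse = "")
      pos <- sample(len, 1)
      w <- extract_window(seqv, pos)
      expect_equal(nchar(w$peptide), 23L)
      expect_equal(substr(w$peptide, 12, 12), substr(seqv, pos, pos))
      # O only as contiguous prefix/suffix; core is a substring of the source
      core <- gsub("^O+|O+$", "", w$peptide)
      expect_false(grepl("O", core))
      expect_true(grepl(core, seqv, fixed = TRUE))
      expect_equal(w$pad_count,
                   max(0, 12 - pos) + max(0, pos + 11 - len))
    }
  })
})

test_that("build_dataset enforces referential integrity and max_pad", {
  prot <- data.frame(id = c("p1", "p2"),
                     sequence = c("MKVLACDEKGHIKLMNPQRSTVWY", "KKK"))
  ann <- data.frame(protein_id = c("p1", "p1", "p2"),
                    position = c(9L, 13L, 1L), label = c(1L, -1L, 1L))
  win <- suppressWarnings(build_dataset(prot, ann))
  expect_equal(nrow(win), 3L)
  expect_equal(win$position, ann$position)  # order preserved, no filter

  filtered <- suppressWarnings(suppressMessages(
    build_dataset(prot, ann, max_pad = 10)
  ))
  expect_true(all(filtered$pad_count <= 10))
  expect_equal(nrow(filtered), 2L)

  bad <- data.frame(protein_id = "ghost", position = 1L, label = 1L)
  expect_error(build_dataset(prot, bad), "ghost")

  # non-lysine centers warn by default, error under strict_center
  nonk <- data.frame(protein_id = "p1", position = 3L, label = 1L)  # V center
  expect_warning(build_dataset(prot, nonk), "not centered on lysine")
  expect_error(build_dataset(prot, nonk, strict_center = TRUE),
               "not centered on lysine")
})

test_that("windows round-trip through TSV", {
  prot <- data.frame(id = "p1", sequence = "MKVLACDEKGHIKLMNPQRSTVWY")
  ann <- data.frame(protein_id = "p1", position = c(9L, 13L),
                    label = c(1L, -1L))
  win <- suppressWarnings(build_dataset(prot, ann))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_windows(win, path)
  back <- read_windows(path)
  expect_equal(back, win, ignore_attr = TRUE)
})
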