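test_that("MatrixMarket triplet round-trips bit-exactly", {
  m <- Matrix::Matrix(toy_counts(c(3, 0, 0, 1, 5, 0), 2, 3), sparse = TRUE)
  dir <- withr::local_tempdir()
  write_counts(m, dir)
  back <- read_counts(file.path(dir, "matrix.mtx"),
                      file.path(dir, "genes.tsv"),
                      file.path(dir, "cells.tsv"))
  expect_identical(as.matrix(back), as.matrix(m))
  expect_identical(dimnames(back), dimnames(m))
  header <- readLines(file.path(dir, "matrix.mtx"), n = 1)
  expect_match(header, "coordinate integer general")
})

test_that("coordinate entries land where the format says", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 2", "1 1 3", "2 2 1"), file.path(dir, "m.mtx"))
  writeLines(c("g1", "g2"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.tsv"))
  m <- read_counts(file.path(dir, "m.mtx"), file.path(dir, "genes.tsv"),
                   file.path(dir, "cells.tsv"))
  expect_equal(unname(as.matrix(m)), matrix(c(3, 0, 0, 1), 2, 2))
})

test_that("duplicate gene symbols are summed into one row", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 3", "1 1 1", "2 1 2", "2 2 5"), file.path(dir, "m.mtx"))
  writeLines(c("g1", "g1"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.tsv"))
  m <- read_counts(file.path(dir, "m.mtx"), file.path(dir, "genes.tsv"),
                   file.path(dir, "cells.tsv"))
  expect_equal(nrow(m), 1)
  expect_equal(unname(as.matrix(m)), matrix(c(3, 5), 1, 2))
})

test_that("dimension mismatches and non-integer values are rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "1 1 2.5"), file.path(dir, "m.mtx"))
  writeLines(c("g1", "g2"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.tsv"))
  expect_error(read_counts(file.path(dir, "m.mtx"),
                           file.path(dir, "genes.tsv"),
                           file.path(dir, "cells.tsv")), "2.5")
  writeLines(c("g1", "g2", "g3"), file.path(dir, "genes3.tsv"))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 1", "1 1 2"), file.path(dir, "m2.mtx"))
  expect_error(read_counts(file.path(dir, "m2.mtx"),
                           file.path(dir, "genes3.tsv"),
                           file.path(dir, "cells.tsv")), "gene ids")
})

test_that("cell annotations are read verbatim with a default group", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.tsv")
  writeLines(c("cell_id\treplicate\tcondition",
               "c1\tr1\tctl", "c2\tr1\tstim", "c3\tr2\tctl"), path)
  ann <- read_cell_annotations(path)
  expect_equal(ann$cell_id, c("c1", "c2", "c3"))
  expect_equal(ann$group, rep("all", 3))

  writeLines(c("cell_id\tcondition", "c1\tctl"), path)
  expect_error(read_cell_annotations(path), "replicate")
  writeLines(c("cell_id\treplicate\tcondition",
               "c1\tr1\tctl", "c1\tr1\tctl"), path)
  expect_error(read_cell_annotations(path), "duplicated")
})

test_that("gene filtering drops under-detected genes and is idempotent", {
  # detection counts per gene: g1 in 3 cells, g2 in 2, g3 in 0
  m <- matrix(c(1, 2, 4, 1, 0, 3, 0, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  f <- filter_genes(m, min_cells = 2)
  expect_equal(rownames(f), c("g1", "g2"))
  expect_equal(rownames(filter_genes(m, min_cells = 3)), "g1")
  expect_equal(nrow(filter_genes(m, min_cells = 4)), 0)
  full <- matrix(1, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_identical(filter_genes(full), full)
  expect_identical(filter_genes(filter_genes(m, 2), 2),
                   filter_genes(m, 2))
})

test_that("group filtering keeps only groups testable in both conditions", {
  ann <- data.frame(
    cell_id = sprintf("c%d", 1:16),
    replicate = "r1",
    condition = c(rep(c("ctl", "stim"), c(4, 4)),      # A: 4/4
                  rep(c("ctl", "stim"), c(3, 2)),      # B: 3/2
                  rep("ctl", 3)),                      # C: 3/0
    group = rep(c("A", "B", "C"), c(8, 5, 3)),
    stringsAsFactors = FALSE)
  m <- toy_counts(1, 2, 16)
  colnames(m) <- ann$cell_id
  out <- filter_groups(m, ann, min_cells_per_condition = 3)
  expect_equal(unique(out$annotations$group), "A")
  expect_equal(ncol(out$counts), 8)
  # boundary group 3/3 retained unchanged
  ann2 <- ann[ann$group == "A", ][1:6, ]
  ann2$condition <- rep(c("ctl", "stim"), each = 3)
  m2 <- m[, ann2$cell_id]
  out2 <- filter_groups(m2, ann2)
  expect_identical(out2$counts, m2)
  # idempotent
  again <- filter_groups(out$counts, out$annotations, 3)
  expect_identical(again$counts, out$counts)
  ann3 <- ann[ann$group == "C", ]
  expect_error(filter_groups(m[, ann3$cell_id], ann3), "no testable groups")
})
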