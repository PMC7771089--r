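test_that("read_gmt parses lines, dedups genes and errors on malformed input", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\tPID\tA\tB\tC", "P2\tPANTHER\tD\tE\tF\tG"), f)
  col <- read_gmt(f)
  expect_s3_class(col, "pathway_collection")
  expect_equal(col$name, c("P1", "P2"))
  expect_equal(col$source, c("PID", "PANTHER"))
  expect_equal(col$genes[[1]], c("A", "B", "C"))

  writeLines("P1\tPID\tA\tA\tB", f)
  expect_warning(col2 <- read_gmt(f), "duplicate")
  expect_equal(col2$genes[[1]], c("A", "B"))

  writeLines(c("P1\tPID\tA", "P2\tonly_two_fields"), f)
  expect_error(read_gmt(f), "line 2", class = "pathmeta_parse_error")

  writeLines(character(0), f)
  expect_error(read_gmt(f), "empty")
})

test_that("write_gmt round-trips a collection up to gene order", {
  col <- pathway_collection(c("B path", "A path"), c("PID", "INOH"),
                            list(c("Z", "A", "M"), c("Q", "B")))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(col, f)
  back <- read_gmt(f)
  expect_equal(back$name, col$name)
  expect_equal(purrr::map(back$genes, sort), purrr::map(col$genes, sort))
  expect_error(write_gmt(col[0, ], f), "empty")
})

test_that("merge_same_name follows the shared-fraction absorption rule", {
  # secondary shares 3/4 = 0.75 > 0.7 of its genes -> absorbed into primary
  col <- pathway_collection(
    c("Folate", "folate "), c("PID", "PANTHER"),
    list(c("A", "B", "C", "D", "E"), c("A", "B", "C", "F"))
  )
  m <- merge_same_name(col)
  expect_equal(nrow(m), 1)
  expect_setequal(m$genes[[1]], c("A", "B", "C", "D", "E", "F"))
  expect_match(m$provenance, "absorbed")

  # secondary shares 1/4 = 0.25 -> its extra genes discarded
  col2 <- pathway_collection(
    c("P", "P"), c("PID", "INOH"),
    list(c("A", "B", "C", "D", "E"), c("A", "F", "G", "H"))
  )
  m2 <- merge_same_name(col2)
  expect_setequal(m2$genes[[1]], c("A", "B", "C", "D", "E"))
  expect_match(m2$provenance, "discarded")

  # no duplicate names -> identity
  col3 <- pathway_collection(c("X", "Y"), c("a", "b"),
                             list(c("A", "B"), c("C", "D")))
  expect_equal(merge_same_name(col3)$genes, col3$genes)
})

test_that("merge_same_name is idempotent and bounded by union/primary", {
  set.seed(11)
  pool <- paste0("g", 1:40)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    genes <- purrr::map(seq_len(k), ~ sample(pool, sample(4:15, 1)))
    col <- pathway_collection(rep("path", k), paste0("src", seq_len(k)), genes)
    once <- merge_same_name(col)
    twice <- merge_same_name(once)
    expect_equal(twice$genes, once$genes)
    primary <- genes[[which.max(lengths(genes))]]
    expect_true(all(primary %in% once$genes[[1]]))
    expect_true(all(once$genes[[1]] %in% unique(unlist(genes))))
  }
})

test_that("pairwise overlap uses |A∩B|/min and drop_smaller resolves violations", {
  col <- pathway_collection(
    c("A", "B"), c("s", "s"),
    list(c("a", "b", "c", "d"), c("a", "b", "c", "e", "f"))
  )
  rep_only <- enforce_pairwise_overlap(col, action = "report")
  expect_equal(nrow(rep_only$violations), 1)
  expect_equal(rep_only$violations$overlap, 3 / 4)  # 0.75 > 0.7
  expect_equal(nrow(rep_only$collection), 2)        # report never mutates

  # disjoint sets: clean
  col2 <- pathway_collection(c("A", "B"), c("s", "s"),
                             list(c("a", "b"), c("c", "d")))
  expect_equal(nrow(enforce_pairwise_overlap(col2)$violations), 0)

  # subset: overlap 1, drop_smaller removes the subset
  col3 <- pathway_collection(c("Small", "Big"), c("s", "s"),
                             list(c("a", "b"), c("a", "b", "c", "d")))
  dropped <- enforce_pairwise_overlap(col3, action = "drop_smaller")
  expect_equal(dropped$collection$name, "Big")
  expect_equal(dropped$violations$dropped, "Small")

  expect_error(enforce_pairwise_overlap(col, threshold = 0), "0, 1")
  expect_error(enforce_pairwise_overlap(col, threshold = 1.5), "0, 1")
})

test_that("after drop_smaller enforcement every pair satisfies the threshold", {
  set.seed(7)
  pool <- paste0("g", 1:30)
  for (rep in 1:15) {
    n_sets <- sample(3:6, 1)
    col <- pathway_collection(
      paste0("P", seq_len(n_sets)), rep("s", n_sets),
      purrr::map(seq_len(n_sets), ~ sample(pool, sample(3:12, 1)))
    )
    out <- enforce_pairwise_overlap(col, threshold = 0.7,
                                    action = "drop_smaller")$collection
    if (nrow(out) >= 2) {
      ov <- pathmeta:::pairwise_overlaps(out)
      expect_true(all(ov$overlap <= 0.7))
    }
  }
})
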