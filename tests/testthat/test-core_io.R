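test_that("class labels map to the two-level vocabulary", {
  tab <- tiny_table()
  expect_equal(as.character(tab$sub_label), c("AD", "SQ", "NONE", "NONE"))
  expect_equal(as.character(tab$top_label), c("NS", "NS", "SC", "NS"))

  syn <- metabolite_table(c("a", "b", "c"), c(0.1, 0.1, 0.1), c(2, 2, 2),
                          c("nsclc", "SCLC", "ad"))
  expect_equal(as.character(syn$top_label), c("NS", "SC", "NS"))
  expect_equal(as.character(syn$sub_label), c("NONE", "NONE", "AD"))

  expect_error(metabolite_table("a", 0.1, 2, "XX"), "unknown class label")
})

test_that("metabolite_table validates records", {
  expect_error(metabolite_table(c("a", "a"), c(0.1, 0.2), c(2, 2), c("AD", "SC")),
               "duplicate")
  expect_error(metabolite_table("a", 1.2, 2, "AD"), "p_value")
  expect_error(metabolite_table("a", 0.5, -1, "AD"), "fold_change")
})

test_that("table reader enforces its format contract", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,pee,fold_change,label", "a,0.1,2,AD"), path)
  expect_error(read_metabolite_table(path), "p_value",
               class = "metabotree_format_error")

  writeLines(c("name,p_value,fold_change,label",
               "a,0.1,2,AD", "b,oops,2,SC"), path)
  expect_error(read_metabolite_table(path), "row\\(s\\): 2")
})

test_that("table round-trips exactly through csv and tsv", {
  tab <- rand_table(10, seed = 11)
  for (dialect in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_metabolite_table(tab, path, dialect)
    back <- read_metabolite_table(path, dialect)
    expect_equal(back, tab)
  }
})

test_that("descriptor matrix reader imputes and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  mat <- rand_matrix(3, 5, seed = 3)
  write_descriptor_matrix(mat, path)
  back <- read_descriptor_matrix(path)
  expect_equal(attr(back, "imputed"), 0)
  expect_equal(unname(back), unname(mat), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(dimnames(back), dimnames(mat))

  # one empty cell -> column-median imputation
  lines <- readLines(path)
  lines[2] <- sub("^(r001,)[^,]*", "\\1", lines[2])
  writeLines(lines, path)
  back2 <- read_descriptor_matrix(path)
  expect_equal(attr(back2, "imputed"), 1)
  expect_equal(back2["r001", "c001"], median(mat[2:3, "c001"]))

  # non-numeric cell -> format error with coordinates
  lines[2] <- sub("^(r001,)[^,]*", "\\1abc", lines[2])
  writeLines(lines, path)
  expect_error(read_descriptor_matrix(path), "row 1, column 'c001'",
               class = "metabotree_format_error")

  writeLines("name,c1", path)
  expect_error(read_descriptor_matrix(path), "empty")
  writeLines(c("metab,c1", "a,1"), path)
  expect_error(read_descriptor_matrix(path), "'name'")
})

test_that("all-missing descriptor columns are dropped", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,c1,c2", "a,1,", "b,2,"), path)
  m <- read_descriptor_matrix(path)
  expect_equal(colnames(m), "c1")
})

test_that("builtin_count descriptors are pure string functions", {
  d <- compute_descriptors(c(methane = "C", ethane = "CC"))
  expect_equal(unname(d[, "n_C"]), c(1, 2))
  expect_gte(ncol(d), 10)

  d2 <- compute_descriptors(c(x = "CC(C(=O)O)N"))
  expect_equal(unname(d2[, "branch_depth"]), 2)
  expect_equal(unname(d2[, "n_double_bond"]), 1)

  expect_error(compute_descriptors(c(a = "CC", b = "")), "b",
               class = "metabotree_validation_error")

  f <- fixture_smiles()
  expect_identical(compute_descriptors(f), compute_descriptors(f))
})

test_that("external_engine backend requires a registered engine", {
  withr::local_options(metabotree.descriptor_engine = NULL)
  expect_error(compute_descriptors("C", backend = "external_engine"),
               "builtin_count", class = "metabotree_capability_error")
  # injected engine is honored
  withr::local_options(metabotree.descriptor_engine = function(s) {
    matrix(nchar(s), ncol = 1, dimnames = list(NULL, "len"))
  })
  d <- compute_descriptors(c(a = "CC", b = "CCC"), backend = "external_engine")
  expect_equal(unname(d[, "len"]), c(2, 3))
})

test_that("labeled_dataset enforces the sub-label invariant", {
  m <- rand_matrix(3, 4, seed = 5)
  expect_error(labeled_dataset(m, c("SC", "SC", "NS"), c("AD", "NONE", "NONE")),
               "requires top_label NS")
  d <- labeled_dataset(m, c("NS", "SC", "NS"), c("AD", "NONE", "SQ"))
  expect_s3_class(d, "labeled_dataset")
  expect_equal(as.character(leaf_labels(d$top_labels, d$sub_labels)),
               c("AD", "SC", "SQ"))
})
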