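test_that("extraction runs end to end and writes per-size rule files", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  out <- file.path(dir, "out")
  report <- run_extract(list(reactions = paths[["reactions"]],
                             structures = paths[["structures"]],
                             lambdas = 1:2, out_dir = out))
  expect_equal(attr(report, "status"), 0L)
  expect_equal(report$n_rules, c(1L, 2L))
  expect_true(file.exists(file.path(out, "rules_lambda1.json")))
  expect_true(file.exists(file.path(out, "rules_lambda2.json")))
  expect_true(file.exists(file.path(out, "extraction_report.tsv")))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_true(all(nchar(unlist(manifest$inputs)) == 32L))  # md5 of each input
  # a rerun reproduces the rule files bit for bit
  out2 <- file.path(dir, "out2")
  run_extract(list(reactions = paths[["reactions"]],
                   structures = paths[["structures"]],
                   lambdas = 1:2, out_dir = out2))
  expect_identical(readLines(file.path(out, "rules_lambda2.json")),
                   readLines(file.path(out2, "rules_lambda2.json")))
})

test_that("a database with one corrupt reaction is reported, others proceed", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  tab <- readr::read_tsv(paths[["reactions"]], show_col_types = FALSE)
  bad <- tibble::tibble(reaction = "BROKEN", metabolite = c("sal", "phnl"),
                        coef = c(-1, 1), reversible = TRUE,
                        pathways = NA_character_, organisms = NA_character_,
                        transport = FALSE)
  tab$transport <- FALSE
  readr::write_tsv(dplyr::bind_rows(tab, bad), paths[["reactions"]])
  out <- file.path(dir, "out")
  report <- run_extract(list(reactions = paths[["reactions"]],
                             structures = paths[["structures"]],
                             lambdas = 1, out_dir = out))
  expect_equal(attr(report, "status"), 0L)
  expect_equal(report$n_rejected, 1L)
  rej <- readr::read_tsv(file.path(out, "rejected_lambda1.tsv"),
                         show_col_types = FALSE)
  expect_equal(rej$reaction, "BROKEN")
})

test_that("design runs write solutions, route tables, and status codes", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  out <- file.path(dir, "design")
  cfg <- list(reactions = paths[["reactions"]],
              structures = paths[["structures"]],
              thermo = paths[["thermo"]],
              lambda = 2, source = "2hipa", target = "phnl",
              exchange = list(`2hipa` = c(-1, -1), phnl = c(1, 1),
                              co2 = c(-10, 10)),
              max_steps = 2, max_solutions = 10, out_dir = out)
  ps <- run_design(cfg)
  expect_equal(attr(ps, "exit_status"), 0L)
  expect_equal(nrow(ps), 4L)
  sol_files <- list.files(out, pattern = "^solution_\\d+\\.json$")
  expect_length(sol_files, 4L)
  routes <- readLines(file.path(out, "routes.txt"))
  expect_true(any(grepl("2hipa -> 2 co2 \\+ phnl", routes)))
  expect_true(any(grepl("step 1:", routes)))
  # infeasible bounds surface as status 3
  cfg_bad <- cfg
  cfg_bad$banned_exchanges <- "co2"
  cfg_bad$out_dir <- file.path(dir, "design_bad")
  ps_bad <- run_design(cfg_bad)
  expect_equal(attr(ps_bad, "exit_status"), 3L)
  # input errors surface as status 4
  cfg_404 <- cfg
  cfg_404$reactions <- file.path(dir, "nope.tsv")
  ps_404 <- run_design(cfg_404)
  expect_equal(attr(ps_404, "exit_status"), 4L)
  expect_match(attr(ps_404, "error"), "nope|exist|open")
})

test_that("the command-line front ends drive extraction and design", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  rbin <- file.path(R.home("bin"), "Rscript")
  cli <- system.file("cli", "moietypath-extract", package = "moietypath")
  out <- file.path(dir, "cliout")
  res <- system2(rbin, c(cli, "--db", paths[["reactions"]],
                         "--structures", paths[["structures"]],
                         "--lambdas", "1,2", "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "rules_lambda2.json")))
  cli2 <- system.file("cli", "moietypath-design", package = "moietypath")
  out2 <- file.path(dir, "clidesign")
  res2 <- suppressWarnings(
    system2(rbin, c(cli2, "--db", paths[["reactions"]],
                    "--structures", paths[["structures"]],
                    "--thermo", paths[["thermo"]],
                    "--lambda", "2", "--source", "2hipa", "--target", "phnl",
                    "--co-exchange", "co2", "--max-steps", "2", "--out", out2),
            stdout = TRUE, stderr = TRUE))
  expect_true(file.exists(file.path(out2, "routes.txt")))
})
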