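# Axitinib practical-example setting (p0, p1, alpha, beta) = (0.05, 0.2, 0.1, 0.1)

tab3_simon <- function() {
  fit <- cached_fit(0.05, 0.2, 0.1, 0.1, "simon")
  result_table(fit$cls, fit$params)
}

test_that("the practical-example Simon table is reproduced", {
  tab <- tab3_simon()
  expect_true(!is.unsorted(rev(tab$n), strictly = TRUE))  # decreasing n
  ref <- data.frame(
    n = c(37, 35, 34, 33, 32),
    n1 = c(12, 13, 14, 15, 18), r1 = 0, r = 3,
    pet1 = c(0.540, 0.513, 0.488, 0.463, 0.397),
    en = c(23.5, 23.7, 24.2, 24.7, 26.4),
    label = c("Optimal", "Admissible", "Inadmissible", "Admissible",
              "Minimax"),
    q_lo = c(0, 0.091, NA, 0.333, 0.630),
    q_hi = c(0.091, 0.333, NA, 0.630, 1))
  for (i in seq_len(nrow(ref))) {
    got <- tab[tab$n == ref$n[i], ]
    expect_equal(nrow(got), 1L)
    expect_equal(unlist(got[c("n1", "r1", "r")]),
                 unlist(ref[i, c("n1", "r1", "r")]),
                 ignore_attr = TRUE)
    expect_equal(got$pet1, ref$pet1[i], tolerance = 1e-6)
    expect_equal(got$en, ref$en[i], tolerance = 1e-6)
    expect_equal(got$label, ref$label[i])
    expect_equal(got$q_lo, ref$q_lo[i], tolerance = 0.005)
    expect_equal(got$q_hi, ref$q_hi[i], tolerance = 0.005)
  }
  # anything beyond the tabulated rows can only be inadmissible
  extra <- tab[!(tab$n %in% ref$n), ]
  expect_true(all(extra$label == "Inadmissible"))
  expect_true(all(is.na(tab$a1)))  # schema keeps a1 for Simon, empty
})

test_that("the practical-example Fleming table is reproduced", {
  fit <- cached_fit(0.05, 0.2, 0.1, 0.1, "fleming")
  tab <- result_table(fit$cls, fit$params)
  mm <- tab[tab$label == "Minimax", ]
  expect_equal(unlist(mm[c("n1", "a1", "r1", "n", "r")]),
               c(n1 = 18, a1 = 0, r1 = 3, n = 31, r = 4))
  expect_equal(mm$n - mm$n1, 13)  # 13 further patients at stage 2
  ref <- data.frame(n = c(37, 35, 32, 31),
                    label = c("Optimal", "Admissible", "Admissible",
                              "Minimax"),
                    en = c(23.0, 23.2, 24.3, 25.1),
                    q_lo = c(0, 0.091, 0.268, 0.444),
                    q_hi = c(0.091, 0.268, 0.444, 1))
  for (i in seq_len(nrow(ref))) {
    got <- tab[tab$n == ref$n[i], ]
    expect_equal(got$label, ref$label[i])
    expect_equal(got$en, ref$en[i], tolerance = 1e-6)
    expect_equal(got$q_lo, ref$q_lo[i], tolerance = 0.005)
    expect_equal(got$q_hi, ref$q_hi[i], tolerance = 0.005)
  }
  expect_true(all(tab$label[!(tab$n %in% ref$n)] == "Inadmissible"))
})

test_that("result tables round-trip through CSV at printed precision", {
  fit <- cached_fit(0.05, 0.2, 0.1, 0.1, "simon")
  tab <- result_table(fit$cls, fit$params)
  f <- withr::local_tempfile(fileext = ".csv")
  write_result_table(tab, f, "csv")
  back <- read.csv(f)
  for (cl in c("alpha_T", "power", "pet1", "en", "n", "n1", "r1", "r",
               "q_lo", "q_hi")) {
    expect_equal(back[[cl]], tab[[cl]], tolerance = 1e-9, info = cl)
  }
  expect_equal(back$label, tab$label)
})

test_that("JSON output parses back to the same rows", {
  fit <- cached_fit(0.05, 0.2, 0.1, 0.1, "simon")
  tab <- result_table(fit$cls, fit$params)
  f <- withr::local_tempfile(fileext = ".json")
  write_result_table(tab, f, "json")
  back <- jsonlite::fromJSON(f)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$en, tab$en)
  expect_equal(back$label, tab$label)
})

test_that("repeated runs are byte-identical", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  r1 <- run_search(0.05, 0.25, 0.05, 0.20, family = "simon", out = f1)
  r2 <- run_search(0.05, 0.25, 0.05, 0.20, family = "simon", out = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(r1$table, r2$table)
})

test_that("curve files carry the EN-vs-n scatter with labels", {
  fit <- cached_fit(0.05, 0.25, 0.05, 0.10, "simon")
  f <- withr::local_tempfile(fileext = ".csv")
  cur <- write_curve(fit$cls, f)
  expect_equal(nrow(cur), 6)
  expect_equal(cur$n[1], 25);  expect_equal(round(cur$en[1], 1), 20.4)
  expect_equal(cur$n[6], 30);  expect_equal(round(cur$en[6], 1), 16.8)
  expect_equal(cur$label[c(1, 6)], c("Minimax", "Optimal"))
  expect_true(file.exists(f))
  expect_equal(nrow(read.csv(f)), 6)
})

test_that("the command-line interface runs its subcommands in-process", {
  f <- withr::local_tempfile(fileext = ".csv")
  status <- cli_main(c("search", "--family", "simon", "--p0", "0.05",
                       "--p1", "0.25", "--alpha", "0.05", "--beta", "0.2",
                       "--out", f))
  expect_identical(status, 0L)
  tab <- read.csv(f)
  expect_equal(tab$n, c(17, 16))
  expect_equal(tab$label, c("Optimal", "Minimax"))

  out <- capture.output(
    status <- cli_main(c("evaluate", "--family", "fleming", "--n1", "9",
                         "--n2", "21", "--a1", "0", "--r1", "4", "--r", "4",
                         "--p0", "0.05", "--p1", "0.25")))
  expect_identical(status, 0L)
  expect_true(any(grepl("alpha_T = 0.0489", out, fixed = TRUE)))

  out <- capture.output(
    status <- cli_main(c("simulate", "--family", "simon", "--n1", "9",
                         "--n2", "8", "--r1", "0", "--r", "2", "--p", "0.05",
                         "--reps", "2000", "--seed", "3")))
  expect_identical(status, 0L)
  expect_true(any(grepl("Monte Carlo", out)))
})

test_that("the CLI reads config files and reports errors by exit status", {
  cfg <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("family = simon", "p0 = 0.05", "p1 = 0.25",
               "alpha = 0.05", "# comment", "beta = 0.2"), cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  expect_identical(cli_main(c("search", "--config", cfg, "--out", f)), 0L)
  expect_equal(read.csv(f)$n, c(17, 16))
  # a flag overrides the config value (beta 0.1 changes the optimum)
  f2 <- withr::local_tempfile(fileext = ".csv")
  expect_identical(cli_main(c("search", "--config", cfg, "--beta", "0.1",
                              "--out", f2)), 0L)
  expect_equal(read.csv(f2)$n[1], 30)

  expect_identical(
    suppressMessages(cli_main(c("search", "--family", "simon",
                                "--p0", "0.3", "--p1", "0.2",
                                "--alpha", "0.05", "--beta", "0.2"))), 1L)
  expect_identical(suppressMessages(cli_main("frobnicate")), 1L)
  expect_identical(suppressMessages(cli_main(character())), 0L)  # usage
})
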