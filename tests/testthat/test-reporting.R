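test_that("the packaged screen reproduces the headline summary counts", {
  rep <- run_screen(provenance = FALSE)
  n <- nrow(rep$table)
  expect_equal(rep$counts$systemic[["likely"]], 8)
  expect_equal(rep$counts$ced[["suitable"]], 9)
  expect_equal(rep$counts$ced[["speculative"]], 2)
  summary_txt <- paste(capture.output(print(rep)), collapse = "\n")
  expect_match(summary_txt, sprintf("systemic likely: 8 / %d \\(15%%\\)", n))
  # efflux annotations ride along for the packaged table
  expect_true(all(c("pgp", "bcrp", "mrp1") %in% names(rep$table)))
})

test_that("screening a user CSV classifies its rows on both routes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,log_p,mw,charge", "TestDrug,1.53,214.10,0"), path)
  rep <- run_screen(path, provenance = FALSE)
  expect_equal(nrow(rep$table), 1)
  expect_equal(rep$table$systemic_label, "likely")
  expect_equal(rep$table$ced_label, "suitable")
  rows <- bbbced:::report_rows(rep)
  expect_equal(rows$systemic_color, "green")
  expect_equal(rows$ced_color, "green")
})

test_that("an empty table yields an empty report with zero counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,log_p,mw,charge", path)
  rep <- run_screen(path, provenance = FALSE)
  expect_equal(nrow(rep$table), 0)
  expect_true(all(rep$counts$systemic == 0))
  expect_no_error(print(rep))
})

test_that("reports serialize to json, csv and markdown", {
  out_json <- withr::local_tempfile(fileext = ".json")
  rep <- run_screen(cfg = rule_config(), format = "json", out = out_json,
                    provenance = FALSE, ascii = TRUE)
  parsed <- jsonlite::fromJSON(out_json, simplifyDataFrame = FALSE)
  expect_length(parsed$drugs, nrow(rep$table))
  expect_equal(parsed$counts$systemic$likely, 8)
  expect_equal(parsed$config$mw_max_da, 500)

  out_csv <- withr::local_tempfile(fileext = ".csv")
  write_screen_report(rep, out_csv, "csv")
  back <- readr::read_csv(out_csv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(rep$table))
  expect_true(all(back$systemic_symbol %in% c("+", "+/-", "-")))

  out_md <- withr::local_tempfile(fileext = ".md")
  write_screen_report(rep, out_md, "markdown")
  md <- readLines(out_md)
  expect_equal(length(md), nrow(rep$table) + 2)
})

test_that("report output is byte-identical when provenance is suppressed", {
  out1 <- withr::local_tempfile(fileext = ".json")
  out2 <- withr::local_tempfile(fileext = ".json")
  run_screen(format = "json", out = out1, provenance = FALSE)
  run_screen(format = "json", out = out2, provenance = FALSE)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("the reference table renders with computed and published labels", {
  md <- render_reference_table("markdown")
  expect_equal(length(md), 53 + 2)
  csv <- render_reference_table("csv", ascii = TRUE)
  tab <- readr::read_csv(I(csv), show_col_types = FALSE)
  expect_equal(nrow(tab), 53)
  expect_true(all(c("computed_systemic", "published_systemic") %in% names(tab)))
  js <- render_reference_table("json")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(nrow(parsed), 53)
})

test_that("rule configurations round-trip through YAML", {
  cfg <- rule_config(mw_max_da = 480, prodrug_systemic_cap = "none",
                     discrepancy_whitelist = tibble::tibble(
                       name = "SomeDrug", route = "ced"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rule_config(cfg, path)
  back <- read_rule_config(path)
  expect_equal(back$mw_max_da, 480)
  expect_equal(back$prodrug_systemic_cap, "none")
  expect_equal(back$discrepancy_whitelist, cfg$discrepancy_whitelist)
  # partial files override single fields only
  writeLines("mw_max_da: 510", path)
  part <- read_rule_config(path)
  expect_equal(part$mw_max_da, 510)
  expect_equal(part$logp_upper, 5)
  writeLines("not_a_field: 1", path)
  expect_error(read_rule_config(path), "unknown config field")
})

test_that("the CLI driver runs its subcommands and signals mismatch status", {
  out <- withr::local_tempfile(fileext = ".json")
  status <- suppressMessages(
    bbbced:::cli_main(c("screen", "--input", "packaged", "--format", "json",
                        "--out", out, "--no-provenance")))
  expect_equal(status, 0L)
  expect_true(file.exists(out))

  expect_equal(suppressMessages(bbbced:::cli_main("reconcile")), 0L)

  # emptied whitelist -> nonzero exit
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  write_rule_config(rule_config(discrepancy_whitelist =
    tibble::tibble(name = character(), route = character())), cfg_path)
  expect_equal(suppressMessages(bbbced:::cli_main(c("reconcile", "--config", cfg_path))), 1L)

  tab_out <- withr::local_tempfile(fileext = ".md")
  expect_equal(bbbced:::cli_main(c("table", "--out", tab_out)), 0L)
  expect_equal(length(readLines(tab_out)), 55)

  sidecar <- withr::local_tempfile(fileext = ".json")
  write_ionization_profiles(
    list(DrugA = ionization_profile(c("acid", "base"), c(4, 9))), sidecar)
  tit_out <- withr::local_tempfile(fileext = ".csv")
  expect_equal(bbbced:::cli_main(c("titrate", "--profile", sidecar, "--name",
                                   "druga", "--ph-step", "1", "--out", tit_out)), 0L)
  tit <- readr::read_csv(tit_out, show_col_types = FALSE)
  expect_equal(nrow(tit), 15)

  expect_equal(suppressMessages(bbbced:::cli_main("nonsense")), 2L)
})
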