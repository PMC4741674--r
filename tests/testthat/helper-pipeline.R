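# shared CLI pipeline driver used by the CLI and determinism tests
run_pipeline <- function(dir, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  glycotype_cli(c("simulate", "--n-train", "30", "--n-test", "10",
                  "--n-valid", "20", "--seed", as.character(seed),
                  "--out-dir", dir))
  glycotype_cli(c("rank", "--profiles", p("train_profiles.tsv"),
                  "--labels", p("train_truth.tsv"),
                  "--isotype", "IgG", "--out", p("ranks.tsv")))
  glycotype_cli(c("fit", "--train", p("train_profiles.tsv"),
                  "--labels", p("train_truth.tsv"),
                  "--out", p("method.yaml"), "--report", p("fit_report.tsv")))
  glycotype_cli(c("type", "--profiles", p("valid_profiles.tsv"),
                  "--method", p("method.yaml"), "--out", p("calls.tsv")))
  glycotype_cli(c("evaluate", "--calls", p("calls.tsv"),
                  "--labels", p("valid_truth.tsv"), "--out", p("report.json")))
  glycotype_cli(c("survival", "--cohort", p("cohort.tsv"),
                  "--out", p("survival.json")))
  invisible(dir)
}
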