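#' Write small deterministic PSM fixture tables
#'
#' Simulates a small labelled data set (N = 500 sample scores, pi0 = 0.7,
#' f_g = 1 by default) and writes it as tab-separated PSM tables in the Crux
#' column convention: `target.tsv` (with an extra `label` column carrying the
#' ground truth) and `entrapment.tsv`. Byte-identical for a given seed;
#' useful for demos and integration tests.
#'
#' @param seed Integer seed.
#' @param outdir Output directory (created if needed).
#' @param config A [simulation_config()]; the default matches the fixture
#'   sizes above.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(seed, outdir,
                          config = simulation_config(N = 500, pi0 = 0.7,
                                                     f_g = 1, seed = seed)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  config$seed <- as.integer(seed)
  ds <- simulate_dataset(config)
  n <- nrow(ds$psms)
  target <- tibble::tibble(
    scan = as.character(seq_len(n)),
    sequence = sprintf("PEP%05dK", seq_len(n)),
    `xcorr score` = format(ds$psms$score, digits = 17, trim = TRUE,
                           scientific = FALSE),
    label = ds$psms$label
  )
  entrap <- tibble::tibble(
    scan = as.character(seq_along(ds$entrapment)),
    sequence = sprintf("ENT%05dK", seq_along(ds$entrapment)),
    `xcorr score` = format(ds$entrapment, digits = 17, trim = TRUE,
                           scientific = FALSE)
  )
  paths <- c(target = file.path(outdir, "target.tsv"),
             entrapment = file.path(outdir, "entrapment.tsv"))
  readr::write_tsv(target, paths[["target"]], progress = FALSE)
  readr::write_tsv(entrap, paths[["entrapment"]], progress = FALSE)
  invisible(paths)
}
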