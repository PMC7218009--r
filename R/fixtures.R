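#' Write small test fixtures
#'
#' Emits a tiny SWC morphology, a constructed hysteretic input-output
#' curve as CSV (with its index values embedded in a comment header), and
#' a constant-rate spike train — the inputs the unit tests exercise
#' parsers and index computations against.
#'
#' @param dir Output directory (created if missing).
#' @param seed Seed for the synthetic morphology fixture.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir = tempdir(), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  swc <- file.path(dir, "mini_motoneuron.swc")
  tree <- synthetic_motoneuron(n_stems = 2, branch_depth = 1,
                               max_path_mm = 0.5, seed = seed)
  write_swc(tree, swc)

  # hysteretic IO fixture: force turns on at 6 nA ascending and persists
  # down to 2 nA descending; 63% of peak at 10 nA -> DCT 4, DCI 4
  grid <- seq(0, 20, by = 0.05)
  asc_force <- pmax(0, pmin(1, (grid - 6) / (10.35 - 6) * 0.657))
  des_force <- pmax(0, pmin(1, (grid - 2) / (6.35 - 2) * 0.657))
  io <- dplyr::bind_rows(
    tibble::tibble(stim = grid, phase = "ascending", force = asc_force,
                   rate = ifelse(grid >= 6, 5 + (grid - 6), 0)),
    tibble::tibble(stim = grid, phase = "descending", force = des_force,
                   rate = ifelse(grid >= 2, 5 + (grid - 2), 0))
  )
  io_path <- file.path(dir, "hysteretic_io.csv")
  writeLines(c("# constructed hysteretic IO curve",
               "# force_initiation=6 force_cessation=2 dct=4"),
             io_path)
  suppressWarnings(utils::write.table(io, io_path, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))

  spikes_path <- file.path(dir, "spikes_10hz.txt")
  writeLines(format(seq(100, 2000, by = 100)), spikes_path)

  invisible(c(swc = swc, io = io_path, spikes = spikes_path))
}

#' Read a fixture IO curve written by [make_fixtures()]
#' @param path CSV path.
#' @return An `io_curve` tibble usable by [thresholds()] and
#'   [compute_indices()].
#' @export
read_io_csv <- function(path) {
  io <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  attr(io, "peak_force") <- max(io$force)
  asc <- io[io$phase == "ascending", ]
  attr(io, "recruitment") <- min(asc$stim[asc$rate > 0])
  des <- io[io$phase == "descending", ]
  attr(io, "derecruitment") <- min(des$stim[des$rate > 0])
  attr(io, "stim_peak") <- max(io$stim)
  class(io) <- c("io_curve", class(io))
  io
}
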