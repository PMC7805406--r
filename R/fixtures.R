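#' Generate the canonical fixture suite
#'
#' Writes a directory of small named networks used throughout examples and
#' tests — the 2-neuron excitatory ring, a zero (silent) matrix, a clamped
#' pair, a set of brute-force-checkable matrices with at most 10 neurons —
#' and, optionally, the larger standard-configuration matrices (1000
#' neurons at E1 = 0.5; 500 and 1000 neurons at E1 = 0.53; 400 neurons at
#' E1 = 0.5).  A `manifest.json` records every fixture with its generation
#' parameters and seed; regeneration with the same seed is byte-identical.
#'
#' @param out_dir output directory (created if missing).
#' @param seed base integer seed.
#' @param include_large also write the large standard-configuration
#'   matrices (slower, bigger files)?  Default `TRUE`.
#' @return invisibly, the manifest as a list.
#' @export
generate_fixture_suite <- function(out_dir, seed = 1L, include_large = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  save_matrix <- function(m, name, params) {
    path <- file.path(out_dir, paste0(name, ".mtx"))
    write_connection_matrix(m, path, format = "matrix-market")
    manifest[[name]] <<- c(list(file = basename(path)), params)
  }
  ring2 <- connection_matrix(rbind(c(0, 1), c(1, 0)))
  save_matrix(ring2, "ring2", list(kind = "2-neuron excitatory ring"))
  write_connection_matrix(ring2, file.path(out_dir, "ring2.tsv"), format = "tsv")
  save_matrix(connection_matrix(matrix(0, 4, 4)), "zero4",
              list(kind = "silent 4-neuron zero matrix"))
  pair <- connection_matrix(rbind(c(0, 1), c(-1, 0)))
  save_matrix(pair, "clamp_pair",
              list(kind = "excitatory/inhibitory pair for clamping demos"))
  for (k in 1:10) {
    n <- 2L + (k - 1L) %% 9L
    sk <- derive_seed(seed, k)
    save_matrix(random_connection_matrix(n, e1 = 0.5, density = 0.6, seed = sk),
                sprintf("brute%02d", k),
                list(kind = "brute-force set", n = n, e1 = 0.5,
                     density = 0.6, seed = sk))
  }
  if (include_large) {
    figs <- list(list(name = "assembly1000_e50", n = 1000L, e1 = 0.5),
                 list(name = "assembly500_e53", n = 500L, e1 = 0.53),
                 list(name = "assembly1000_e53", n = 1000L, e1 = 0.53),
                 list(name = "assembly400_e50", n = 400L, e1 = 0.5))
    for (f in figs) {
      sk <- derive_seed(seed, 100L + f$n)
      save_matrix(random_connection_matrix(f$n, e1 = f$e1, density = 1, seed = sk),
                  f$name, list(kind = "standard configuration", n = f$n,
                               e1 = f$e1, density = 1, seed = sk))
    }
  }
  manifest <- list(seed = seed, include_large = include_large,
                   fixtures = manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a spike raster with its provenance sidecar
#'
#' The raster goes to CSV (one row per time step, one column per neuron)
#' and a JSON sidecar records seed, init, cycle information and package
#' version, so every output carries its provenance.
#'
#' @param raster a [simulate_assembly()] result.
#' @param path CSV output path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return invisibly, the sidecar list.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  utils::write.csv(raster$spikes, path, row.names = FALSE)
  cyc <- raster_cycle(raster)
  sidecar <- list(
    n = raster$n, steps = raster$steps, seed = raster$seed,
    init = if (identical(raster$init, "single")) "single" else "explicit",
    cycle = cyc,
    package = as.character(utils::packageVersion("neuroassembly")))
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sidecar)
}
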