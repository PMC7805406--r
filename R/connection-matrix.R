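#' Connection matrices of unitized synapses
#'
#' A connection matrix is the whole parameterization of a simplified neural
#' assembly: a square matrix `M` with entries in \{-1, 0, 1\}, where
#' `M[i, j]` is the synapse from neuron `i` to neuron `j` (+1 excitatory,
#' -1 inhibitory, 0 absent).  `connection_matrix()` validates and classes an
#' existing matrix; [random_connection_matrix()] draws one at random.
#'
#' @param entries a square numeric matrix with entries in \{-1, 0, 1\}.
#' @param meta optional list of generation parameters (kept as an attribute;
#'   e.g. `e1`, `density`, `seed` for synthetic matrices).
#' @return an object of class `connection_matrix` (a base matrix with a
#'   `meta` attribute).
#' @examples
#' m <- connection_matrix(rbind(c(0, 1), c(-1, 0)))
#' m
#' @export
connection_matrix <- function(entries, meta = list()) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "double"
  validate_entries(entries)
  structure(entries, meta = meta, class = c("connection_matrix", "matrix"))
}

validate_entries <- function(entries) {
  if (nrow(entries) != ncol(entries)) {
    stop_param("connection matrix must be square, got ",
               nrow(entries), " x ", ncol(entries))
  }
  if (nrow(entries) < 1L) {
    stop_param("connection matrix must have at least one neuron")
  }
  bad <- which(!(entries %in% c(-1, 0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(entries)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(entries)) + 1L
    stop_param("invalid entry ", format(entries[bad[1L]]), " at (", i, ", ", j,
               "): entries must be -1, 0 or 1 (", length(bad), " invalid)")
  }
  invisible(entries)
}

#' @export
print.connection_matrix <- function(x, ...) {
  n <- nrow(x)
  nz <- sum(x != 0)
  e1 <- if (nz > 0) sum(x == 1) / nz else NA_real_
  cat(sprintf("<connection_matrix> %d neurons, %d synapses (density %.3f)\n",
              n, nz, nz / (n * n)))
  if (!is.na(e1)) {
    cat(sprintf("  excitatory fraction E1 = %.3f, inhibitory E-1 = %.3f\n",
                e1, 1 - e1))
  }
  meta <- attr(x, "meta")
  if (length(meta)) {
    cat("  meta:", paste(names(meta), unlist(meta), sep = "=", collapse = ", "),
        "\n")
  }
  if (n <= 12L) print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Generate a random unitized connection matrix
#'
#' Each eligible entry is nonzero independently with probability `density`;
#' nonzero entries are +1 with probability `e1` and -1 otherwise.  Together
#' the excitatory fraction `e1` (so `E1 + E-1 = 1`) and the neuron count are
#' the parameters that govern assembly stability.
#'
#' @param n number of neurons (positive integer).
#' @param e1 fraction of excitatory (+1) synapses among nonzero entries,
#'   in \[0, 1\].
#' @param density probability that an eligible entry is nonzero, in (0, 1\].
#' @param allow_self should self-connections (diagonal) be allowed?
#'   Defaults to `FALSE`.
#' @param seed optional integer seed; for a fixed seed the draw is
#'   deterministic and the caller's RNG state is untouched.
#' @return a [connection_matrix()] with generation parameters in `meta`.
#' @examples
#' m <- random_connection_matrix(50, e1 = 0.5, seed = 1)
#' attr(m, "meta")$e1
#' @export
random_connection_matrix <- function(n, e1 = 0.5, density = 1, allow_self = FALSE,
                                     seed = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop_param("`n` must be a positive integer")
  }
  if (density <= 0 || density > 1) {
    stop_param("`density` must be in (0, 1]")
  }
  if (e1 < 0 || e1 > 1) {
    stop_param("`e1` must be in [0, 1]")
  }
  n <- as.integer(n)
  entries <- with_seed(seed, {
    nz <- matrix(stats::runif(n * n) < density, n, n)
    sgn <- matrix(ifelse(stats::runif(n * n) < e1, 1, -1), n, n)
    ifelse(nz, sgn, 0)
  })
  if (!allow_self) diag(entries) <- 0
  connection_matrix(entries,
                    meta = list(n = n, e1 = e1, density = density,
                                allow_self = allow_self, seed = seed))
}

#' Read or write a connection matrix
#'
#' Matrices are exchanged either as Matrix Market coordinate files (only the
#' -1/+1 entries are stored; absent entries are 0) or as dense tab-separated
#' files.  Reading validates strictly: the matrix must be square and every
#' entry must be -1, 0 or 1.
#'
#' @param path file path.
#' @param format `"matrix-market"`, `"tsv"`, or `"auto"` (by file
#'   extension: `.mtx` is Matrix Market, anything else TSV).
#' @param m a [connection_matrix()].
#' @return `read_connection_matrix()` returns a [connection_matrix()];
#'   `write_connection_matrix()` returns `path` invisibly.
#' @export
read_connection_matrix <- function(path, format = c("auto", "matrix-market", "tsv")) {
  format <- resolve_format(path, match.arg(format))
  if (format == "matrix-market") {
    mm <- try(Matrix::readMM(path), silent = TRUE)
    if (inherits(mm, "try-error")) {
      stop_param("failed to parse Matrix Market file '", path, "': ",
                 attr(mm, "condition")$message)
    }
    entries <- as.matrix(mm)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "numeric")
    entries <- as.matrix(tab)
    dimnames(entries) <- NULL
  }
  connection_matrix(entries, meta = list(source = path, format = format))
}

#' @rdname read_connection_matrix
#' @export
write_connection_matrix <- function(m, path, format = c("auto", "matrix-market", "tsv")) {
  stopifnot(inherits(m, "connection_matrix"))
  format <- resolve_format(path, match.arg(format))
  if (format == "matrix-market") {
    Matrix::writeMM(Matrix::Matrix(unclass(m), sparse = TRUE), path)
  } else {
    utils::write.table(unclass(m), path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) "matrix-market" else "tsv"
}
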