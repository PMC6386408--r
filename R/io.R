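#' Save a sweep result to a directory
#'
#' Writes a lossless plain-text serialisation: `grid.tsv` (0-based deme
#' coordinates and allele id), `origins.tsv` (allele id, 0-based origin
#' coordinates, origin time), `meta.json` (configuration, seed, event
#' counts, total time, schema and package versions) and `manifest.json`
#' listing every file written.  Coordinates follow the package convention:
#' 1D positions are integers in `[0, L)`; 2D lattices are row-major
#' `(x, y)` pairs.
#'
#' @param result A `"sweep_result"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a named list of file paths.
#' @export
save_sweep <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- result$config$L; d <- result$config$dim

  grid <- as.integer(result$grid)
  gtab <- if (d == 1L)
    data.frame(x = seq_along(grid) - 1L, allele = grid)
  else
    data.frame(x = (seq_along(grid) - 1L) %% L,
               y = (seq_along(grid) - 1L) %/% L, allele = grid)
  paths <- c(grid = file.path(dir, "grid.tsv"),
             origins = file.path(dir, "origins.tsv"),
             meta = file.path(dir, "meta.json"),
             manifest = file.path(dir, "manifest.json"))
  write.table(gtab, paths[["grid"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(result$origins, paths[["origins"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  meta <- list(schema_version = 1L,
               package_version = as.character(packageVersion("softsweeps")),
               config = result$config,
               event_counts = as.list(result$event_counts),
               total_time = result$total_time,
               n_demes = length(grid),
               n_alleles = nrow(result$origins))
  jsonlite::write_json(meta, paths[["meta"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(list(schema_version = 1L,
                            files = as.list(basename(paths[-4L]))),
                       paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(as.list(paths))
}

#' Load a sweep result saved by [save_sweep()]
#'
#' Validates the schema version, reconstructs the lattice, and checks the
#' stored tables for corruption (every deme present exactly once, every
#' origin deme carrying its own allele, masses summing to `L^dim`).
#'
#' @param dir Directory written by [save_sweep()].
#' @return A `"sweep_result"`.
#' @export
load_sweep <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("not a sweep directory: missing meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L)
    stop("unsupported schema version: ", format(meta$schema_version))
  L <- as.integer(meta$config$L); d <- as.integer(meta$config$dim)

  gtab <- read.table(file.path(dir, "grid.tsv"), header = TRUE, sep = "\t")
  origins <- read.table(file.path(dir, "origins.tsv"), header = TRUE, sep = "\t")
  N <- as.numeric(L)^d
  if (nrow(gtab) != N)
    stop("corrupt sweep file: grid has ", nrow(gtab), " rows, expected ", N)
  idx <- if (d == 1L) gtab$x else gtab$x + L * gtab$y
  if (anyNA(idx) || anyNA(gtab$allele) || !setequal(idx, 0:(N - 1)))
    stop("corrupt sweep file: deme coordinates are not a complete lattice")
  grid <- integer(N)
  grid[idx + 1L] <- as.integer(gtab$allele)
  oidx <- if (d == 1L) origins$x else origins$x + L * origins$y
  if (any(grid[oidx + 1L] != origins$allele))
    stop("corrupt sweep file: origin demes do not carry their own allele")
  if (nrow(origins) != meta$n_alleles ||
      !setequal(unique(grid), seq_len(nrow(origins))))
    stop("corrupt sweep file: allele labels inconsistent with origins table")
  if (d == 2L) grid <- matrix(grid, nrow = L)

  structure(list(grid = grid,
                 origins = origins,
                 event_counts = unlist(meta$event_counts),
                 total_time = meta$total_time,
                 config = meta$config),
            class = "sweep_result")
}
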