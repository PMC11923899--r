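#' @importFrom stats aggregate cor cor.test cutree fisher.test hclust median
#'   p.adjust pchisq phyper qnorm rbinom rhyper rnorm rpois runif sd setNames
#'   wilcox.test
#' @importFrom utils combn head read.delim write.table
NULL

CELL_COLUMNS <- c("cell_id", "x", "y", "section_id", "layer",
                  "region", "class", "subclass")

CLASS_LEVELS <- c("excitatory", "inhibitory")

#' Construct a validated cell table
#'
#' A cell table is the package's central container: one row per neuron with
#' 2-D coordinates in micrometres (per-section frame), a section identifier,
#' cortical layer 1-6, a brain-region label, a class
#' (`"excitatory"`/`"inhibitory"`) and a finer subclass label. Geometry is
#' only ever computed within a section; coordinates of different sections
#' live in unrelated frames.
#'
#' @param df data.frame with columns `cell_id`, `x`, `y`, `section_id`,
#'   `layer`, `region`, `class`, `subclass`.
#' @param subclass_vocab optional named list with elements `excitatory` and
#'   `inhibitory` giving the subclass vocabulary per class; defaults to the
#'   labels observed in `df`. Unknown labels found in `df` are appended.
#' @return A `cell_table`: a data.frame with canonical column order and a
#'   `subclass_vocab` attribute.
#' @export
cell_table <- function(df, subclass_vocab = NULL) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(CELL_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("cell table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[CELL_COLUMNS]
  df$cell_id <- as.character(df$cell_id)
  df$section_id <- as.character(df$section_id)
  df$region <- as.character(df$region)
  df$subclass <- as.character(df$subclass)
  df$class <- tolower(as.character(df$class))
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  df$layer <- as.integer(df$layer)

  bad <- !is.finite(df$x) | !is.finite(df$y)
  if (any(bad)) {
    stop("non-finite coordinates in row(s): ",
         paste(head(which(bad), 5L), collapse = ", "),
         " (", sum(bad), " rows total)")
  }
  bad <- is.na(df$layer) | df$layer < 1L | df$layer > 6L
  if (any(bad)) {
    stop("layer outside 1-6 in row(s): ",
         paste(head(which(bad), 5L), collapse = ", "),
         " (", sum(bad), " rows total)")
  }
  bad <- !(df$class %in% CLASS_LEVELS)
  if (any(bad)) {
    stop("class must be 'excitatory' or 'inhibitory'; offending row(s): ",
         paste(head(which(bad), 5L), collapse = ", "))
  }
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id(s): ",
         paste(head(unique(df$cell_id[duplicated(df$cell_id)]), 5L), collapse = ", "))
  }

  vocab <- list(
    excitatory = sort(unique(df$subclass[df$class == "excitatory"])),
    inhibitory = sort(unique(df$subclass[df$class == "inhibitory"]))
  )
  if (!is.null(subclass_vocab)) {
    vocab$excitatory <- union(subclass_vocab$excitatory, vocab$excitatory)
    vocab$inhibitory <- union(subclass_vocab$inhibitory, vocab$inhibitory)
  }
  rownames(df) <- NULL
  structure(df, subclass_vocab = vocab, class = c("cell_table", "data.frame"))
}

#' @export
print.cell_table <- function(x, ...) {
  v <- attr(x, "subclass_vocab")
  cat(sprintf("<cell_table> %d cells | %d section(s) | layers %s\n",
              nrow(x), length(unique(x$section_id)),
              paste(sort(unique(x$layer)), collapse = ",")))
  cat(sprintf("  excitatory: %d  inhibitory: %d\n",
              sum(x$class == "excitatory"), sum(x$class == "inhibitory")))
  cat("  subclass vocab E: ", paste(v$excitatory, collapse = ", "), "\n", sep = "")
  cat("  subclass vocab I: ", paste(v$inhibitory, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subclass vocabulary of a cell table
#'
#' @param table a `cell_table`.
#' @return Named list with character vectors `excitatory` and `inhibitory`.
#' @export
subclass_vocab <- function(table) {
  v <- attr(table, "subclass_vocab")
  if (is.null(v)) {
    v <- list(excitatory = sort(unique(table$subclass[table$class == "excitatory"])),
              inhibitory = sort(unique(table$subclass[table$class == "inhibitory"])))
  }
  v
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a cell table from TSV/CSV
#'
#' The header must declare the eight canonical columns (`cell_id`, `x`, `y`,
#' `section_id`, `layer`, `region`, `class`, `subclass`); extra columns are
#' dropped. Coordinates are taken as micrometres. Class tokens are matched
#' case-insensitively and stored lower-case.
#'
#' @param path path to a delimited text file.
#' @param delim field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A validated [cell_table()].
#' @export
read_cell_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- read.delim(path, sep = delim, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(CELL_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num <- suppressWarnings(list(x = as.numeric(df$x), y = as.numeric(df$y),
                               layer = as.numeric(df$layer)))
  bad <- which(!is.finite(num$x) | !is.finite(num$y) | !is.finite(num$layer))
  if (length(bad) > 0L) {
    stop("row-level validation error: non-numeric coordinate/layer in row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  df$x <- num$x; df$y <- num$y; df$layer <- as.integer(num$layer)
  cell_table(df)
}

#' Write a cell table as TSV
#'
#' Writes the canonical eight columns, tab-separated, with deterministic byte
#' output for a fixed table so exports can be diffed across runs.
#'
#' @param table a `cell_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  stopifnot(inherits(table, "cell_table"))
  write.table(as.data.frame(table)[CELL_COLUMNS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a brain-region annotation table
#'
#' Maps region labels to a lobe, to membership in functional systems (default
#' mode network, visual, somatosensory) and to an optional cortical hierarchy
#' level. Expected columns: `region`, optional `lobe`, optional `systems`
#' (semicolon/comma-separated subset of `dmn`, `visual`, `somatosensory`) and
#' optional `level` (numeric). Regions absent from the file resolve to "no
#' lobe, no system, no level".
#'
#' @param path path to a delimited text file.
#' @param delim field delimiter; `NULL` auto-detects.
#' @return A `region_annotation` object supporting [region_systems()],
#'   [region_level()] and [region_lobe()].
#' @export
read_region_annotation <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- detect_delim(path)
  df <- read.delim(path, sep = delim, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  if (!"region" %in% names(df)) stop("schema error: file lacks column: region")
  if (!"lobe" %in% names(df)) df$lobe <- NA_character_
  if (!"systems" %in% names(df)) df$systems <- ""
  if (!"level" %in% names(df)) df$level <- NA_character_
  region_annotation(df)
}

#' Construct a region annotation from a data.frame
#'
#' @param df data.frame with columns `region` and optionally `lobe`,
#'   `systems`, `level` (see [read_region_annotation()]).
#' @return A `region_annotation` object.
#' @export
region_annotation <- function(df) {
  stopifnot(is.data.frame(df), "region" %in% names(df))
  df <- as.data.frame(df)
  if (is.null(df$lobe)) df$lobe <- NA_character_
  if (is.null(df$systems)) df$systems <- ""
  if (is.null(df$level)) df$level <- NA_real_
  df$region <- as.character(df$region)
  df$lobe <- as.character(df$lobe)
  df$level <- suppressWarnings(as.numeric(df$level))
  sys_list <- lapply(as.character(df$systems), function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    toks <- tolower(trimws(strsplit(s, "[;,|]")[[1]]))
    toks <- toks[nzchar(toks)]
    bad <- setdiff(toks, c("dmn", "visual", "somatosensory"))
    if (length(bad) > 0L) stop("unknown system label(s): ", paste(bad, collapse = ", "))
    sort(unique(toks))
  })
  if (anyDuplicated(df$region)) {
    dup <- unique(df$region[duplicated(df$region)])
    for (r in dup) {
      idx <- which(df$region == r)
      same <- length(unique(df$lobe[idx])) == 1L &&
        length(unique(vapply(sys_list[idx], paste, "", collapse = ";"))) == 1L &&
        length(unique(df$level[idx])) == 1L
      if (!same) stop("conflicting duplicate annotation rows for region: ", r)
    }
    keep <- !duplicated(df$region)
    sys_list <- sys_list[keep]
    df <- df[keep, , drop = FALSE]
  }
  structure(list(region = df$region, lobe = df$lobe,
                 systems = sys_list, level = df$level),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("<region_annotation> %d regions (%d with hierarchy level)\n",
              length(x$region), sum(is.finite(x$level))))
  invisible(x)
}

#' Functional systems a region belongs to
#'
#' @param annotation a `region_annotation`.
#' @param region character vector of region labels.
#' @return For a single region, a character vector (possibly empty); for
#'   several, a list of such vectors. Unannotated regions return `character(0)`.
#' @export
region_systems <- function(annotation, region) {
  stopifnot(inherits(annotation, "region_annotation"))
  idx <- match(region, annotation$region)
  out <- lapply(idx, function(i) if (is.na(i)) character(0) else annotation$systems[[i]])
  if (length(region) == 1L) out[[1]] else out
}

#' Hierarchy level of a region
#'
#' @inheritParams region_systems
#' @return Numeric vector; `NA` for unannotated or unleveled regions.
#' @export
region_level <- function(annotation, region) {
  stopifnot(inherits(annotation, "region_annotation"))
  annotation$level[match(region, annotation$region)]
}

#' Lobe of a region
#'
#' @inheritParams region_systems
#' @return Character vector; `NA` for unannotated regions.
#' @export
region_lobe <- function(annotation, region) {
  stopifnot(inherits(annotation, "region_annotation"))
  annotation$lobe[match(region, annotation$region)]
}

#' Is a region in a given functional system?
#'
#' @inheritParams region_systems
#' @param system one of `"dmn"`, `"visual"`, `"somatosensory"`.
#' @return Logical vector.
#' @export
region_in_system <- function(annotation, region, system) {
  system <- match.arg(tolower(system), c("dmn", "visual", "somatosensory"))
  idx <- match(region, annotation$region)
  vapply(idx, function(i) {
    if (is.na(i)) FALSE else system %in% annotation$systems[[i]]
  }, logical(1))
}

#' Analysis configuration for cluster detection
#'
#' Bundles the sliding-window geometry and the permutation-test settings.
#' Species presets follow the window configurations used for the macaque
#' (1000 um window, 100 um step), the finer macaque validation scan
#' (400/100) and the mouse cortex (400/20); the permutation default is
#' 10 000 shuffles with significance at raw p < 0.05.
#'
#' @param window_size window side length in micrometres.
#' @param step grid step in micrometres; must satisfy `0 < step <= window_size`.
#' @param n_perm number of label permutations (>= 1).
#' @param alpha significance level in (0, 1); windows with p < alpha count
#'   as enriched.
#' @param seed integer seed controlling all permutation draws.
#' @param stratum `"section_layer"` (default: shuffle within each section and
#'   layer) or `"layer"` (pool sections of a layer).
#' @param min_window_n smallest window occupancy that is tested (default 1).
#' @return An `analysis_config` list.
#' @seealso [preset()] for the named species configurations.
#' @export
analysis_config <- function(window_size = 1000, step = 100, n_perm = 10000,
                            alpha = 0.05, seed = 1L,
                            stratum = c("section_layer", "layer"),
                            min_window_n = 1L) {
  stratum <- match.arg(stratum)
  if (!(window_size >= step && step > 0)) {
    stop("window/step must satisfy window_size >= step > 0")
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  structure(list(window_size = window_size, step = step,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), stratum = stratum,
                 min_window_n = as.integer(min_window_n)),
            class = "analysis_config")
}

#' Named analysis presets
#'
#' `"macaque"` uses a 1000 um x 1000 um window stepped by 100 um;
#' `"macaque_check"` is the finer 400 um / 100 um validation configuration;
#' `"mouse"` uses 400 um windows stepped by 20 um. All default to 10 000
#' permutations at alpha = 0.05.
#'
#' @param name one of `"macaque"`, `"macaque_check"`, `"mouse"` (hyphens
#'   accepted in place of underscores).
#' @param ... overrides passed to [analysis_config()] (e.g. `n_perm`, `seed`).
#' @return An `analysis_config`.
#' @export
preset <- function(name, ...) {
  key <- gsub("-", "_", tolower(name))
  params <- switch(key,
    macaque       = list(window_size = 1000, step = 100),
    macaque_check = list(window_size = 400,  step = 100),
    mouse         = list(window_size = 400,  step = 20),
    stop("unknown preset '", name,
         "'; available: macaque, macaque_check, mouse")
  )
  do.call(analysis_config, c(params, list(...)))
}
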