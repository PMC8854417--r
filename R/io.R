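#' Read a trait table from CSV/TSV
#'
#' Reads either a species-level table (long format: `species_id`, `trait`,
#' `mean`, `se`, optional `n`) or a specimen-level table of raw linear SEM
#' measurements. Specimen tables have one row per measured individual with
#' columns `species_id`, `specimen_id`, the head and eye chords (`H_width`,
#' `E_widthA`, `E_height`, `E_widthL`), `OC_diameter`, the antennal parts
#' (`F_length`, `P_length`, `A_length`), and one or more ommatidial hexagon
#' diameter columns `OM_diameter_1`, `OM_diameter_2`, ... All lengths are in
#' micrometres. Missing cells are allowed (empty or NA) and stay `NA`;
#' present values must be strictly positive numbers.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from the header
#'   line) with a header row.
#' @param level `"species"` or `"specimen"`.
#' @return A [species_traits] table, or a data frame of specimen
#'   measurements with class `"specimen_measurements"`.
#' @export
read_trait_table <- function(path, level = c("species", "specimen")) {
  level <- match.arg(level)
  raw <- read_delim_sniff(path)
  if (nrow(raw) == 0) stop("no records in ", path)
  if (level == "species") {
    for (col in intersect(c("mean", "se", "n"), names(raw))) {
      raw[[col]] <- parse_numeric_column(raw, col)
    }
    return(species_traits(raw))
  }
  specimen_measurements(raw)
}

#' @rdname read_trait_table
#' @param x Data frame of raw specimen rows (see `read_trait_table`).
#' @export
specimen_measurements <- function(x) {
  if (nrow(x) == 0) stop("no records")
  if (!all(c("species_id", "specimen_id") %in% names(x))) {
    stop("specimen table needs species_id and specimen_id columns")
  }
  x$species_id <- normalize_species_id(x$species_id)
  if (anyDuplicated(x$specimen_id)) {
    stop("duplicate specimen_id: ", x$specimen_id[duplicated(x$specimen_id)][1])
  }
  num_cols <- setdiff(names(x), c("species_id", "specimen_id"))
  for (col in num_cols) {
    x[[col]] <- parse_numeric_column(x, col)
    if (any(!is.na(x[[col]]) & x[[col]] <= 0)) {
      bad <- which(!is.na(x[[col]]) & x[[col]] <= 0)[1]
      stop("non-positive measurement in column ", col, ", row ", bad)
    }
  }
  om_cols <- grep("^OM_diameter", names(x), value = TRUE)
  if (length(om_cols) == 0) stop("no OM_diameter_* columns in specimen table")
  class(x) <- unique(c("specimen_measurements", class(x)))
  x
}

parse_numeric_column <- function(df, col) {
  v <- df[[col]]
  if (is.numeric(v)) return(v)
  v <- trimws(as.character(v))
  v[v == ""] <- NA
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad) > 0) {
    stop("non-numeric value '", v[bad[1]], "' in column ", col,
         ", row ", bad[1])
  }
  out
}

read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("no records in ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = TRUE,
                    strip.white = TRUE)
}

#' Write a species trait table to CSV
#'
#' Values are written at full precision (17 significant digits), so a
#' write/read round trip is lossless.
#'
#' @param traits A [species_traits] table.
#' @param path Output file path.
#' @export
write_trait_table <- function(traits, path) {
  out <- as.data.frame(traits)[, c("species_id", "trait", "mean", "se", "n")]
  for (col in c("mean", "se")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate an ultrametric phylogeny
#'
#' Reads a Newick tree, requires branch lengths, a strictly bifurcating
#' topology and ultrametricity (all root-to-tip path lengths equal within a
#' relative tolerance of the tree depth). Polytomies and non-ultrametric
#' trees are hard errors rather than silently fixed. Optionally rescales the
#' root depth to 1, the convention used throughout the package (relative
#' time units).
#'
#' @param path Newick file path.
#' @param rescale_depth Rescale branch lengths so the root-to-tip depth is
#'   exactly 1 (default `TRUE`).
#' @param tol Relative ultrametricity tolerance (default `1e-6` of depth).
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path, rescale_depth = TRUE, tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  validate_tree(tree, tol = tol)
  if (rescale_depth) tree <- rescale_tree_depth(tree) else tree
}

#' @rdname read_tree
#' @param tree An [ape::phylo] object.
#' @export
validate_tree <- function(tree, tol = 1e-6) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.binary(tree)) stop("tree contains polytomies; resolve before use")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  dev <- max(depths) - min(depths)
  if (dev > tol * max(depths)) {
    stop("tree is not ultrametric: max root-to-tip deviation ",
         format(dev), " exceeds tolerance ", format(tol * max(depths)))
  }
  invisible(tree)
}

#' @rdname read_tree
#' @export
rescale_tree_depth <- function(tree, depth = 1) {
  d <- max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
  tree$edge.length <- tree$edge.length / d * depth
  tree
}

#' Read a regime assignment table
#'
#' CSV/TSV with columns `species_id`, `regime` (values `SAT` / `NON_SAT`)
#' and optionally `substrategy`. The substrategy (necrophagous, hole
#' searcher, stalker/lurker, satellite) is descriptive metadata only and is
#' never used in computation.
#'
#' @param path File path.
#' @return Data frame with class `"regime_assignment"`.
#' @export
read_regimes <- function(path) {
  raw <- read_delim_sniff(path)
  regime_assignment(raw)
}

#' @rdname read_regimes
#' @param x Data frame with `species_id` and `regime` columns.
#' @export
regime_assignment <- function(x) {
  if (nrow(x) == 0) stop("no records in regime table")
  if (!all(c("species_id", "regime") %in% names(x))) {
    stop("regime table needs species_id and regime columns")
  }
  x$species_id <- normalize_species_id(x$species_id)
  if (anyDuplicated(x$species_id)) {
    stop("duplicate species in regime table: ",
         x$species_id[duplicated(x$species_id)][1])
  }
  bad <- setdiff(unique(x$regime), c("SAT", "NON_SAT"))
  if (length(bad) > 0) stop("unknown regime value: ", bad[1])
  class(x) <- unique(c("regime_assignment", class(x)))
  x
}

#' Packaged study fixtures
#'
#' Returns the transcribed published species tables: `"table1"` — head width
#' and the five visual-system traits (E_area, OM_area, OM_number, the
#' interommatidial angle delta_gamma, OC_diameter) for the 18 miltogrammine
#' species; `"table2"` — the four
#' antennal traits (F_length, P_length, A_length, ANT_length); `"regimes"` —
#' the host-finding strategy of each species (10 satellite, 8 non-satellite,
#' with substrategy where the source text identifies it). Values are stored
#' exactly as printed (one decimal place).
#'
#' @param name One of `"table1"`, `"table2"`, `"regimes"`.
#' @return A [species_traits] table or a [regime_assignment] data frame.
#' @examples
#' t1 <- builtin_fixture("table1")
#' subset(t1, species_id == "Miltogramma_punctata" & trait == "OM_number")
#' @export
builtin_fixture <- function(name = c("table1", "table2", "regimes")) {
  if (!is.character(name) || length(name) != 1 ||
      !(name %in% c("table1", "table2", "regimes"))) {
    stop("unknown fixture name: ", paste(name, collapse = ", "))
  }
  file <- switch(name,
    table1  = "table1_visual.csv",
    table2  = "table2_antennal.csv",
    regimes = "regimes.csv"
  )
  path <- system.file("extdata", file, package = "flyvis", mustWork = TRUE)
  if (name == "regimes") read_regimes(path) else read_trait_table(path)
}
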