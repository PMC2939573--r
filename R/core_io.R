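#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# Sister-pair tables
# ---------------------------------------------------------------------------

#' Construct a SisterPairTable from a data frame
#'
#' @param pairs data.frame holding the columns listed under
#'   [SisterPairTable-class]. Extra columns (e.g. footnote flags) are kept.
#' @return a validated [SisterPairTable-class]; row order is preserved.
#' @examples
#' SisterPairTable(data.frame(
#'   pair_id = "Apiomorpha", galler_name = "Apiomorpha", n_galler = 150,
#'   host_age_galler = 65, nongaller_name = "Ourococcus", n_nongaller = 3,
#'   host_age_nongaller = 104))
#' @export
SisterPairTable <- function(pairs) {
  pairs <- as.data.frame(pairs)
  .checkPairFrame(pairs)
  # counts stay numeric (integer-valued): simulated clades can exceed the
  # 32-bit integer range
  for (f in c("n_galler", "n_nongaller")) pairs[[f]] <- round(as.numeric(pairs[[f]]))
  for (f in c("host_age_galler", "host_age_nongaller")) pairs[[f]] <- as.numeric(pairs[[f]])
  pairs$pair_id <- as.character(pairs$pair_id)
  rownames(pairs) <- NULL
  new("SisterPairTable", pairs = pairs)
}

#' Read a sister-pair table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row carrying at least
#' the columns \code{pair_id}, \code{galler_name}, \code{n_galler},
#' \code{host_age_galler}, \code{nongaller_name}, \code{n_nongaller},
#' \code{host_age_nongaller}. Missing columns, non-integer counts and
#' negative ages raise validation errors naming the offending row and field.
#'
#' @param path path to the CSV file. The packaged comparison table is at
#'   \code{table1Path()}.
#' @return a [SisterPairTable-class]; row order is preserved.
#' @examples
#' tab <- readSisterTable(table1Path())
#' nPairs(tab)
#' @export
readSisterTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  SisterPairTable(df)
}

#' Write a sister-pair table to CSV
#' @param x a [SisterPairTable-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeSisterTable <- function(x, path) {
  stopifnot(is(x, "SisterPairTable"))
  utils::write.csv(x@pairs, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @describeIn nPairs number of rows in the pair table.
#' @export
setMethod("nPairs", "SisterPairTable", function(x) nrow(x@pairs))

#' @describeIn pairIds pair ids in table order.
#' @export
setMethod("pairIds", "SisterPairTable", function(x) x@pairs$pair_id)

#' Coerce a SisterPairTable to a data.frame
#' @param x a [SisterPairTable-class].
#' @param row.names,optional,... passed on for S3 compatibility; unused.
#' @return the underlying data.frame.
#' @export
as.data.frame.SisterPairTable <- function(x, row.names = NULL, optional = FALSE, ...) {
  x@pairs
}

#' Extract one sister pair by id
#' @param x a [SisterPairTable-class].
#' @param id a pair id.
#' @return the pair as a named list (one `SisterPair` record).
#' @examples
#' getPair(readSisterTable(table1Path()), "Apiomorpha")$n_galler
#' @export
getPair <- function(x, id) {
  stopifnot(is(x, "SisterPairTable"))
  i <- match(id, x@pairs$pair_id)
  if (is.na(i)) stop("unknown pair_id: ", id, call. = FALSE)
  as.list(x@pairs[i, , drop = FALSE])
}

setMethod("show", "SisterPairTable", function(object) {
  cat(sprintf("SisterPairTable with %d galler / non-galler pair(s)\n",
              nrow(object@pairs)))
  print(utils::head(object@pairs[, c("pair_id", "n_galler", "n_nongaller",
                                     "host_age_galler", "host_age_nongaller")], 6))
  if (nrow(object@pairs) > 6) cat("...\n")
})

# ---------------------------------------------------------------------------
# Richness trees
# ---------------------------------------------------------------------------

# tip depths (distance from root) of a phylo object
.tipDepths <- function(phy) {
  d <- ape::node.depth.edgelength(phy)
  d[seq_along(phy$tip.label)]
}

#' Construct a RichnessTree from a phylo object and a richness map
#'
#' Ultrametricity is checked on construction: all root-to-tip path lengths
#' must agree within \code{tol * rootAge} (the tolerance is relative because
#' branch lengths are in arbitrary time units after root-height rescaling).
#'
#' @param phy an ape \code{phylo} with branch lengths.
#' @param richness named numeric vector of integer richness (>= 1); names
#'   must cover exactly the tip labels.
#' @param tol relative ultrametricity tolerance (default \code{1e-6}).
#' @return a [RichnessTree-class].
#' @export
RichnessTree <- function(phy, richness, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape 'phylo' object", call. = FALSE)
  if (is.null(phy$edge.length)) stop("tree must have branch lengths", call. = FALSE)
  tips <- phy$tip.label
  if (is.null(names(richness))) stop("richness must be a named vector", call. = FALSE)
  unknown <- setdiff(names(richness), tips)
  if (length(unknown)) {
    stop("richness map names tip(s) absent from the tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(tips, names(richness))
  if (length(missing)) {
    stop("tip(s) missing from the richness map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  depths <- .tipDepths(phy)
  root_age <- max(depths)
  dev <- diff(range(depths))
  if (dev > tol * root_age) {
    stop(sprintf(
      "tree is not ultrametric: maximum root-to-tip deviation %.6g exceeds tolerance %.3g x root age (%.6g)",
      dev, tol, root_age), call. = FALSE)
  }
  r <- as.numeric(richness)[match(tips, names(richness))]
  names(r) <- tips
  new("RichnessTree", phy = phy, richness = r, rootAge = root_age)
}

#' Read a richness-annotated ultrametric tree
#'
#' Richness is carried in a sidecar CSV (columns \code{tip}, \code{richness})
#' to keep the Newick standard; a fallback encoding \code{"label|count"} in
#' the tip names themselves is also accepted when no map is supplied.
#' Polytomies are permitted and flagged with a message.
#'
#' @param newick path to a Newick file, or a Newick string.
#' @param richness a named numeric vector, a path to a two-column CSV
#'   (\code{tip,richness}), or \code{NULL} to parse \code{"label|count"}
#'   tip names.
#' @param tol relative ultrametricity tolerance.
#' @return a [RichnessTree-class].
#' @examples
#' readRichnessTree("((A:1,B:1):1,C:2);", c(A = 1, B = 1, C = 1))
#' readRichnessTree("((A|4:1,B|1:1):1,C|10:2);")
#' @export
readRichnessTree <- function(newick, richness = NULL, tol = 1e-6) {
  phy <- if (length(newick) == 1L && grepl("\\(", newick) && !file.exists(newick)) {
    ape::read.tree(text = newick)
  } else {
    ape::read.tree(newick)
  }
  if (is.null(phy)) stop("could not parse Newick input", call. = FALSE)
  if (is.null(richness)) {
    lab <- phy$tip.label
    if (!all(grepl("|", lab, fixed = TRUE))) {
      stop("no richness map supplied and tip labels are not 'label|count' encoded",
           call. = FALSE)
    }
    parts <- strsplit(lab, "|", fixed = TRUE)
    counts <- suppressWarnings(as.numeric(vapply(parts, function(p) p[length(p)], "")))
    if (any(!is.finite(counts))) stop("malformed 'label|count' tip name", call. = FALSE)
    phy$tip.label <- vapply(parts, function(p) paste(p[-length(p)], collapse = "|"), "")
    richness <- stats::setNames(counts, phy$tip.label)
  } else if (is.character(richness) && length(richness) == 1L) {
    m <- utils::read.csv(richness, stringsAsFactors = FALSE)
    if (ncol(m) < 2L) stop("richness CSV needs columns tip,richness", call. = FALSE)
    richness <- stats::setNames(as.numeric(m[[2L]]), as.character(m[[1L]]))
  }
  if (!ape::is.binary(phy)) message("note: tree contains polytomies")
  RichnessTree(phy, richness, tol = tol)
}

#' Write a richness tree to Newick (+ optional sidecar CSV)
#'
#' With \code{richnessPath = NULL} the richness is encoded into the tip
#' labels as \code{"label|count"}; otherwise the plain Newick and a
#' two-column CSV map are written.
#'
#' @param x a [RichnessTree-class].
#' @param newickPath output Newick path.
#' @param richnessPath optional CSV path for the richness map.
#' @return invisibly, the paths written.
#' @export
writeRichnessTree <- function(x, newickPath, richnessPath = NULL) {
  stopifnot(is(x, "RichnessTree"))
  phy <- x@phy
  if (is.null(richnessPath)) {
    phy$tip.label <- paste0(phy$tip.label, "|",
                            format(x@richness, trim = TRUE, scientific = FALSE))
    ape::write.tree(phy, file = newickPath)
    return(invisible(newickPath))
  }
  ape::write.tree(phy, file = newickPath)
  utils::write.csv(data.frame(tip = names(x@richness), richness = x@richness,
                              row.names = NULL),
                   richnessPath, row.names = FALSE, quote = TRUE)
  invisible(c(newickPath, richnessPath))
}

#' @describeIn tipRichness richness counts of a richness tree.
#' @export
setMethod("tipRichness", "RichnessTree", function(x) x@richness)

#' @describeIn rootAge root age of a richness tree.
#' @export
setMethod("rootAge", "RichnessTree", function(x) x@rootAge)

#' @describeIn stemAges parent-node ages of the tips.
#' @export
setMethod("stemAges", "RichnessTree", function(x) {
  phy <- x@phy
  ntip <- length(phy$tip.label)
  depths <- ape::node.depth.edgelength(phy)
  parent <- phy$edge[match(seq_len(ntip), phy$edge[, 2L]), 1L]
  ages <- x@rootAge - depths[parent]
  stats::setNames(ages, phy$tip.label)
})

#' @describeIn branchingTimes internal node ages of a richness tree, sorted
#'   descending (the first entry equals the root age).
#' @export
setMethod("branchingTimes", "RichnessTree", function(x) {
  bt <- ape::branching.times(x@phy)
  sort(unname(bt), decreasing = TRUE)
})

#' @describeIn scaleRootHeight rescale a richness tree; idempotent at the
#'   target and multiplicative under composition.
#' @export
setMethod("scaleRootHeight", "RichnessTree", function(x, target) {
  stopifnot(is.numeric(target), length(target) == 1L, is.finite(target),
            target > 0)
  phy <- x@phy
  phy$edge.length <- phy$edge.length * (target / x@rootAge)
  RichnessTree(phy, x@richness)
})

setMethod("show", "RichnessTree", function(object) {
  cat(sprintf("RichnessTree: %d terminal clade(s), total richness %d, root age %.4g\n",
              length(object@richness), as.integer(sum(object@richness)),
              object@rootAge))
  if (!ape::is.binary(object@phy)) cat("  (contains polytomies)\n")
})
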