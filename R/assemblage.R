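ELEMENT_TYPES <- c("double_valved", "left_valve", "right_valve",
                   "shell_with_apex", "shell_without_apex", "plate", "whole")
HIGHER_GROUPS <- c("bivalve", "gastropod", "polyplacophoran", "scaphopod",
                   "other")

# Which element types each higher group may carry.
.allowedElements <- list(
  bivalve = c("double_valved", "left_valve", "right_valve"),
  gastropod = c("shell_with_apex", "shell_without_apex"),
  polyplacophoran = "plate",
  scaphopod = "whole",
  other = "whole"
)

TRAIT_DIMENSIONS <- c("feeding_guild", "substrate_relation",
                      "host_association", "weed_association")

#' Closed trait vocabularies for the functional categorization
#'
#' Main categories of the four functional dimensions used to characterize
#' molluscan ecology: feeding guild, organism-substrate relation, host
#' association and weed association.
#'
#' @return named list of character vectors.
#' @export
traitVocabulary <- function() {
  list(
    feeding_guild = c("carnivore", "chemosymbiotic", "detritivore", "grazing",
                      "filter-feeding", "herbivore", "scavenging"),
    substrate_relation = c("epifauna", "epifauna_on_vegetation", "infauna",
                           "semi-infauna", "epibiont_ectoparasite", "nestler",
                           "terrestrial_freshwater"),
    host_association = c("free_living", "host_associated"),
    weed_association = c("none", "strictly_seagrass", "seagrass_and_algae",
                         "mainly_seagrass")
  )
}

#' Minimum number of bivalve individuals from shell elements
#'
#' Applies the counting rule for bivalves: the number of double-valved
#' (articulated) specimens plus the larger of the loose left- and
#' right-valve counts.
#'
#' @param records data.frame with columns `element` and `count`, all
#'   elements bivalve element types.
#' @return MNI (non-negative number).
#' @examples
#' countBivalveMni(data.frame(
#'   element = c("double_valved", "left_valve", "right_valve"),
#'   count = c(3, 5, 4)))  # 8
#' @export
countBivalveMni <- function(records) {
  if (nrow(records) == 0L) return(0)
  bad <- setdiff(records$element, .allowedElements$bivalve)
  if (length(bad))
    stop("non-bivalve element type(s) in bivalve MNI count: ",
         paste(bad, collapse = ", "))
  s <- function(el) sum(records$count[records$element == el])
  s("double_valved") + max(s("left_valve"), s("right_valve"))
}

#' Count gastropod individuals
#'
#' Gastropod shells count as individuals only if at least the apex is
#' preserved; apex-less shells are ignored.
#' @inheritParams countBivalveMni
#' @export
countGastropods <- function(records) {
  if (nrow(records) == 0L) return(0)
  bad <- setdiff(records$element, .allowedElements$gastropod)
  if (length(bad))
    stop("non-gastropod element type(s): ", paste(bad, collapse = ", "))
  sum(records$count[records$element == "shell_with_apex"])
}

#' Count polyplacophoran individuals
#'
#' Chitons disarticulate into eight plates; individuals are counted as the
#' number of plates divided by eight, kept fractional.
#' @inheritParams countBivalveMni
#' @export
countPolyplacophorans <- function(records) {
  if (nrow(records) == 0L) return(0)
  bad <- setdiff(records$element, "plate")
  if (length(bad))
    stop("polyplacophorans are counted from plates only, got: ",
         paste(bad, collapse = ", "))
  sum(records$count) / 8
}

#' Individuals from the shell elements of one taxon in one increment
#'
#' Dispatches the group-specific counting rule: bivalve MNI
#' (double-valved + max(left, right)), apex-bearing gastropod shells,
#' polyplacophoran plates / 8, and whole shells for scaphopods and other
#' groups.
#'
#' @param records data.frame with `element` and `count`.
#' @param higherGroup one of "bivalve", "gastropod", "polyplacophoran",
#'   "scaphopod", "other".
#' @export
countIndividuals <- function(records, higherGroup) {
  higherGroup <- match.arg(higherGroup, HIGHER_GROUPS)
  switch(higherGroup,
    bivalve = countBivalveMni(records),
    gastropod = countGastropods(records),
    polyplacophoran = countPolyplacophorans(records),
    {
      bad <- setdiff(records$element, "whole")
      if (length(bad))
        stop(higherGroup, " specimens must be 'whole' shells, got: ",
             paste(bad, collapse = ", "))
      sum(records$count)
    }
  )
}

#' Build an increments-by-taxa assemblage from raw shell-element records
#'
#' Validates the element records (element types must be permitted for the
#' taxon's higher group, counts positive), applies the counting protocol per
#' taxon and depth increment, and assembles a [CoreAssemblage-class] with
#' taxa as rows and depth increments (ordered shallow to deep) as columns.
#'
#' @param records data.frame with columns `taxon`, `higher_group`, `element`,
#'   `count`, `depth_top`, `depth_bottom` (optionally `record_id`).
#' @param traits optional taxon trait table (column `taxon` plus the four
#'   trait dimensions); attached as `rowData`.
#' @return a `CoreAssemblage`.
#' @export
buildAssemblage <- function(records, traits = NULL) {
  need <- c("taxon", "higher_group", "element", "count",
            "depth_top", "depth_bottom")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("specimen records are missing columns: ",
         paste(missing, collapse = ", "))
  if (nrow(records) == 0L) stop("no specimen records supplied")
  if (any(records$count <= 0)) {
    stop("non-positive counts in records rows ",
         paste(which(records$count <= 0), collapse = ", "))
  }
  badGroup <- !records$higher_group %in% HIGHER_GROUPS
  if (any(badGroup))
    stop("unknown higher_group in rows ",
         paste(which(badGroup), collapse = ", "))
  okEl <- mapply(function(g, e) e %in% .allowedElements[[g]],
                 records$higher_group, records$element)
  if (!all(okEl))
    stop("element type not permitted for higher group in rows ",
         paste(which(!okEl), collapse = ", "))
  grp <- vapply(split(records$higher_group, records$taxon),
                function(g) {
                  if (length(unique(g)) > 1L)
                    stop("taxon assigned to more than one higher group")
                  g[1]
                }, character(1))
  inc <- unique(records[, c("depth_top", "depth_bottom")])
  inc <- inc[order(inc$depth_top), , drop = FALSE]
  taxa <- sort(unique(records$taxon))
  counts <- matrix(0, nrow = length(taxa), ncol = nrow(inc),
                   dimnames = list(taxa, sprintf("%g-%gcm", inc$depth_top,
                                                 inc$depth_bottom)))
  key <- match(paste(records$depth_top, records$depth_bottom),
               paste(inc$depth_top, inc$depth_bottom))
  for (split_i in split(seq_len(nrow(records)),
                        list(records$taxon, key), drop = TRUE)) {
    r <- records[split_i, , drop = FALSE]
    counts[r$taxon[1], key[split_i[1]]] <-
      countIndividuals(r, grp[[r$taxon[1]]])
  }
  rowDat <- S4Vectors::DataFrame(taxon = taxa, higher_group = unname(grp[taxa]))
  if (!is.null(traits)) {
    m <- match(taxa, traits$taxon)
    for (dim in intersect(TRAIT_DIMENSIONS, names(traits)))
      rowDat[[dim]] <- traits[[dim]][m]
  }
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = rowDat,
    colData = S4Vectors::DataFrame(depth_top = inc$depth_top,
                                   depth_bottom = inc$depth_bottom,
                                   row.names = colnames(counts))
  )
  new("CoreAssemblage", se)
}

#' @export
setMethod("abundanceMatrix", "CoreAssemblage", function(x) {
  t(assay(x, "counts"))
})

#' @export
setMethod("depthIntervals", "CoreAssemblage", function(x) {
  cd <- colData(x)
  data.frame(depth_top = cd$depth_top, depth_bottom = cd$depth_bottom,
             row.names = colnames(x))
})

#' @export
setMethod("show", "CoreAssemblage", function(object) {
  cat("CoreAssemblage:", nrow(object), "taxa x", ncol(object),
      "depth increments\n")
  cd <- colData(object)
  cat(sprintf("  depths %g-%g cm, %.6g individuals\n",
              min(cd$depth_top), max(cd$depth_bottom),
              sum(assay(object, "counts"))))
  if (ncol(rowData(object)) > 2)
    cat("  traits:", paste(setdiff(colnames(rowData(object)),
                                   c("taxon", "higher_group")),
                           collapse = ", "), "\n")
})

#' Merge adjacent thin top-of-core slices pairwise
#'
#' The reference sampling design slices the uppermost 20 cm into 2-cm
#' increments and the rest into 5-cm increments; for analysis the ten 2-cm
#' slices are merged pairwise into five 4-cm slices (38 subsamples become 33
#' analysis increments). Counts are summed per pair; thicker slices are
#' untouched. An unpaired thin slice is an error.
#'
#' @param x a `CoreAssemblage`.
#' @param thickness slice thickness (cm) to merge, default 2.
#' @return a `CoreAssemblage` with merged columns.
#' @export
mergeTopSlices <- function(x, thickness = 2) {
  stopifnot(is(x, "CoreAssemblage"))
  cd <- colData(x)
  thin <- which(abs((cd$depth_bottom - cd$depth_top) - thickness) < 1e-9)
  if (length(thin) == 0L) return(x)
  thin <- thin[order(cd$depth_top[thin])]
  if (length(thin) %% 2L != 0L)
    stop("odd number of ", thickness, "-cm slices; cannot pair them")
  first <- thin[seq(1, length(thin), by = 2)]
  second <- thin[seq(2, length(thin), by = 2)]
  if (any(abs(cd$depth_bottom[first] - cd$depth_top[second]) > 1e-9))
    stop("thin slices are not adjacent pairs; cannot merge")
  cts <- assay(x, "counts")
  merged <- cts[, first, drop = FALSE] + cts[, second, drop = FALSE]
  keep <- setdiff(seq_len(ncol(x)), thin)
  newCounts <- cbind(merged, cts[, keep, drop = FALSE])
  newTop <- c(cd$depth_top[first], cd$depth_top[keep])
  newBot <- c(cd$depth_bottom[second], cd$depth_bottom[keep])
  ord <- order(newTop)
  newCounts <- newCounts[, ord, drop = FALSE]
  colnames(newCounts) <- sprintf("%g-%gcm", newTop[ord], newBot[ord])
  se <- SummarizedExperiment(
    assays = list(counts = newCounts), rowData = rowData(x),
    colData = S4Vectors::DataFrame(depth_top = newTop[ord],
                                   depth_bottom = newBot[ord],
                                   row.names = colnames(newCounts)))
  new("CoreAssemblage", se)
}

#' Aggregate an assemblage by a functional-trait dimension
#'
#' Sums individuals per trait category within each increment and derives
#' relative abundances (category total / increment total). Relative rows sum
#' to 1 where the increment total is positive and are `NA` for empty
#' increments.
#'
#' @param x a `CoreAssemblage` whose `rowData` carries the trait dimension,
#'   or a plain increments-by-taxa matrix plus a `traits` table.
#' @param dimension one of `"feeding_guild"`, `"substrate_relation"`,
#'   `"host_association"`, `"weed_association"` (or any rowData column).
#' @param traits trait table (needed only when `x` is a bare matrix).
#' @param missing `"error"` (default) to fail on taxa without a trait value,
#'   or `"unclassified"` to pool them into an "unclassified" category.
#' @return list with `absolute` and `relative` increments-by-category
#'   matrices.
#' @export
aggregateByTrait <- function(x, dimension, traits = NULL,
                             missing = c("error", "unclassified")) {
  missing <- match.arg(missing)
  if (is(x, "CoreAssemblage")) {
    mat <- abundanceMatrix(x)
    rd <- rowData(x)
    if (!dimension %in% colnames(rd))
      stop("trait dimension '", dimension, "' not present in rowData")
    cat_by_taxon <- setNames(as.character(rd[[dimension]]), rd$taxon)
  } else {
    mat <- as.matrix(x)
    if (is.null(traits)) stop("a traits table is required for matrix input")
    cat_by_taxon <- setNames(as.character(traits[[dimension]]), traits$taxon)
  }
  cats <- cat_by_taxon[colnames(mat)]
  if (anyNA(cats)) {
    if (missing == "error")
      stop("taxa without a '", dimension, "' value: ",
           paste(colnames(mat)[is.na(cats)], collapse = ", "))
    cats[is.na(cats)] <- "unclassified"
  }
  absolute <- t(rowsum(t(mat), group = cats))
  tot <- rowSums(absolute)
  relative <- absolute / tot
  relative[tot == 0, ] <- NA_real_
  list(absolute = absolute, relative = relative)
}

#' Drop increments below a minimum sample size
#'
#' Increments whose total individual count is below `threshold` are removed
#' (the boundary is inclusive: a total exactly at the threshold is kept) and
#' logged in `metadata(x)$excluded`.
#'
#' @param x a `CoreAssemblage`.
#' @param threshold minimum N (default 50 individuals).
#' @return the filtered `CoreAssemblage`; excluded increments (name, total)
#'   are recorded in its metadata.
#' @export
filterMinN <- function(x, threshold = 50) {
  stopifnot(is(x, "CoreAssemblage"))
  tot <- colSums(assay(x, "counts"))
  drop <- tot < threshold
  excluded <- data.frame(increment = colnames(x)[drop], total = tot[drop],
                         row.names = NULL)
  if (all(drop))
    warning("every increment falls below the minimum N of ", threshold)
  out <- x[, !drop]
  out <- as(out, "CoreAssemblage")
  S4Vectors::metadata(out)$excluded <- excluded
  out
}
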