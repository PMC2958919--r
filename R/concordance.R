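## Gene-tree/species concordance: monophyly assessment, coalescence-
## depth profiling of discordant haplotypes, and the three-criterion
## classification of discordance causes (incomplete lineage sorting vs
## introgression vs recent divergence).

.tipSpecies <- function(tr, meta) {
  sp <- meta$species_label[match(tr$tip.label, meta$specimen_id)]
  direct <- is.na(sp) & tr$tip.label %in% meta$species_label
  sp[direct] <- tr$tip.label[direct]   # tips labelled by species
  if (anyNA(sp))
    stop("tip(s) not mapped to any species: ",
         paste(tr$tip.label[is.na(sp)], collapse = ", "))
  sp
}

.cladeTips <- function(tr, node) {
  n <- length(tr$tip.label)
  if (node <= n) return(node)
  kids <- tr$edge[tr$edge[, 1L] == node, 2L]
  unlist(lapply(kids, .cladeTips, tr = tr))
}

#' Assess per-species monophyly in a gene tree
#'
#' For each species the MRCA of its tips is found; *intruder* tips are
#' heterospecific tips inside that clade, *outlier* tips are
#' conspecific tips outside the species' core clade (the largest clade
#' containing only tips of the species, holding the plurality of
#' them). A species is monophyletic iff it has neither; it is called
#' paraphyletic when the intruders themselves form a single clade and
#' polyphyletic otherwise.
#'
#' @param tr rooted `phylo`; every tip label must map to a
#'   `specimen_id` (or directly to a `species_label`) in `meta`.
#' @param meta specimen table with `specimen_id` and `species_label`.
#' @return data.frame (one row per species): `species`, `nTips`,
#'   `status`, `intruders`, `outliers` (comma-separated tip labels).
#' @export
assessMonophyly <- function(tr, meta) {
  sp <- .tipSpecies(tr, meta)
  ntip <- length(tr$tip.label)
  ## tip sets of every clade, once
  nodes <- unique(tr$edge[, 1L])
  cladeSets <- lapply(nodes, .cladeTips, tr = tr)
  names(cladeSets) <- nodes
  out <- lapply(unique(sp), function(s) {
    tips <- which(sp == s)
    if (length(tips) == 1L)
      return(data.frame(species = s, nTips = 1L,
                        status = "monophyletic", intruders = "",
                        outliers = ""))
    mrca <- ape::getMRCA(tr, tips)
    clade <- cladeSets[[as.character(mrca)]]
    intruders <- setdiff(clade, tips)
    ## core clade: largest clade consisting only of this species' tips
    mono <- cladeSets[vapply(cladeSets, function(ct)
      all(sp[ct] == s), logical(1))]
    core <- if (length(mono))
      mono[[which.max(lengths(mono))]] else integer(0)
    best <- if (length(core) >= 1L) core else tips[1L]
    outliers <- setdiff(tips, best)
    status <- if (!length(intruders) && !length(outliers))
      "monophyletic"
    else {
      intrMono <- length(intruders) &&
        (length(intruders) == 1L ||
           all(cladeSets[[as.character(ape::getMRCA(tr, intruders))]]
               %in% intruders))
      if (intrMono && !length(setdiff(tips, clade)))
        "paraphyletic" else "polyphyletic"
    }
    data.frame(species = s, nTips = length(tips), status = status,
               intruders = paste(tr$tip.label[intruders],
                                 collapse = ","),
               outliers = paste(tr$tip.label[outliers],
                                collapse = ","))
  })
  do.call(rbind, out)
}

#' Relative coalescence depths of discordant haplotypes
#'
#' For a species that is not monophyletic in the gene tree, each
#' discordance event is the smallest clade joining a discordant tip
#' (an intruder inside the species' clade, or a conspecific outlier)
#' with its nearest heterospecific neighbours. The event depth is that
#' clade's height -- the maximum root-to-tip path within the clade
#' measured from the clade's root -- divided by the tree's root height
#' (maximum root-to-tip path, outgroup tips excluded when flagged via
#' an `outgroup` logical column in `meta`). Deep events (near 1) are
#' the signature of retained ancestral polymorphism; shallow events
#' (near 0) of recent introgression or recent divergence. No
#' ultrametricity is assumed.
#'
#' @param tr rooted `phylo` with branch lengths.
#' @param meta specimen table with `specimen_id`, `species_label` and
#'   optionally a logical `outgroup` column.
#' @param species the focal (nonmonophyletic) species label.
#' @return data.frame: `species`, `tip`, `role` (intruder/outlier),
#'   `node`, `relDepth` in [0, 1]; one row per discordant tip, tips
#'   sharing an event node share its depth.
#' @export
coalescenceDepthProfile <- function(tr, meta, species) {
  if (is.null(tr$edge.length))
    stop("tree must have branch lengths")
  sp <- .tipSpecies(tr, meta)
  ntip <- length(tr$tip.label)
  depths <- ape::node.depth.edgelength(tr)   # root-to-node distance
  keepTips <- seq_len(ntip)
  if ("outgroup" %in% names(meta)) {
    og <- meta$specimen_id[which(meta$outgroup)]
    keepTips <- which(!(tr$tip.label %in% og))
  }
  rootHeight <- max(depths[keepTips])
  if (rootHeight <= 0) stop("tree has zero root height")
  mono <- assessMonophyly(tr, meta)
  row <- mono[mono$species == species, ]
  if (!nrow(row)) stop("species not in tree: ", species)
  disc <- c(strsplit(row$intruders, ",")[[1L]],
            strsplit(row$outliers, ",")[[1L]])
  disc <- disc[nzchar(disc)]
  if (!length(disc))
    return(data.frame(species = character(), tip = character(),
                      role = character(), node = integer(),
                      relDepth = numeric()))
  roles <- c(rep("intruder",
                 length(strsplit(row$intruders, ",")[[1L]][
                   nzchar(strsplit(row$intruders, ",")[[1L]])])),
             rep("outlier",
                 length(strsplit(row$outliers, ",")[[1L]][
                   nzchar(strsplit(row$outliers, ",")[[1L]])])))
  parent <- integer(max(tr$edge))
  parent[tr$edge[, 2L]] <- tr$edge[, 1L]
  rootNode <- ntip + 1L
  out <- lapply(seq_along(disc), function(j) {
    tip <- match(disc[j], tr$tip.label)
    tipSp <- sp[tip]
    node <- tip
    repeat {                            # walk up to the joining clade
      node <- parent[node]
      ct <- .cladeTips(tr, node)
      if (any(sp[ct] != tipSp) || node == rootNode) break
    }
    height <- max(depths[intersect(.cladeTips(tr, node), keepTips)]) -
      depths[node]
    data.frame(species = species, tip = disc[j], role = roles[j],
               node = node, relDepth = height / rootHeight)
  })
  do.call(rbind, out)
}

#' Classify causes of gene-tree/species discordance
#'
#' Combines three criteria per species: the depth of the discordant
#' coalescences in the gene tree, evidence of admixture in the
#' multilocus data, and (as a reported score, not a gate) the
#' geographic spread of the specimens involved. The decision table:
#' deep coalescences (relative depth >= `depthThreshold`) with no
#' admixture (max foreign ancestry < `admixThreshold`) indicate
#' incomplete lineage sorting; shallow coalescences with admixture in
#' neighbouring individuals indicate recent divergence or
#' introgression (deliberately not resolved further); the two
#' conflicting combinations are labelled ambiguous, as is any
#' nonmonophyletic species lacking admixture results. Monophyletic
#' species are concordant. The geographic criterion stays advisory
#' because a concentration of shared markers near a range boundary can
#' also reflect a pre-existing cline.
#'
#' @param mono output of [assessMonophyly()].
#' @param depths named list: per nonmonophyletic species, the
#'   data.frame from [coalescenceDepthProfile()] (the species' summary
#'   depth is the median event depth).
#' @param admix named list: per species, the `report` data.frame of
#'   [pairwiseAdmixture()] (own/foreign ancestry per individual).
#' @param meta specimen table; when `latitude`/`longitude` are present
#'   a geographic score is reported: mean pairwise great-circle
#'   distance (km) between the specimens carrying the discordant
#'   haplotypes, and the species' range span.
#' @param depthThreshold relative depth at or above which a
#'   coalescence counts as deep (default 0.5).
#' @param admixThreshold foreign-ancestry fraction at or above which
#'   admixture evidence is claimed (default 0.10).
#' @return data.frame per species: `species`, `status`, `medianDepth`,
#'   `maxForeignAncestry`, `geoCarrierKm`, `geoRangeKm`, `label`,
#'   `reason`.
#' @export
classifyDiscordance <- function(mono, depths = list(), admix = list(),
                                meta = NULL, depthThreshold = 0.5,
                                admixThreshold = 0.10) {
  rows <- lapply(seq_len(nrow(mono)), function(r) {
    s <- mono$species[r]
    base <- data.frame(species = s, status = mono$status[r],
                       medianDepth = NA_real_,
                       maxForeignAncestry = NA_real_,
                       geoCarrierKm = NA_real_, geoRangeKm = NA_real_,
                       label = "concordant", reason = "")
    if (mono$status[r] == "monophyletic") return(base)
    dp <- depths[[s]]
    base$medianDepth <- if (!is.null(dp) && nrow(dp))
      stats::median(dp$relDepth) else NA_real_
    ad <- admix[[s]]
    if (is.null(ad)) {
      base$label <- "ambiguous"
      base$reason <- "no admixture results supplied"
      return(base)
    }
    base$maxForeignAncestry <- max(ad$foreign_ancestry)
    if (!is.null(meta) && all(c("latitude", "longitude") %in%
                              names(meta)) && !is.null(dp) && nrow(dp)) {
      carriers <- meta[meta$specimen_id %in% dp$tip, , drop = FALSE]
      own <- meta[meta$species_label == s, , drop = FALSE]
      gcMean <- function(df) {
        if (nrow(df) < 2L || anyNA(df$latitude)) return(NA_real_)
        pts <- as.matrix(df[, c("longitude", "latitude")])
        dd <- geosphere::distm(pts) / 1000
        mean(dd[upper.tri(dd)])
      }
      base$geoCarrierKm <- gcMean(carriers)
      base$geoRangeKm <- if (nrow(own) >= 2L && !anyNA(own$latitude)) {
        pts <- as.matrix(own[, c("longitude", "latitude")])
        max(geosphere::distm(pts)) / 1000
      } else NA_real_
    }
    if (is.na(base$medianDepth)) {
      base$label <- "ambiguous"
      base$reason <- "no depth profile supplied"
      return(base)
    }
    deep <- base$medianDepth >= depthThreshold
    admixed <- base$maxForeignAncestry >= admixThreshold
    base$label <- if (deep && !admixed) "incomplete-lineage-sorting"
      else if (!deep && admixed) "recent-divergence-or-introgression"
      else "ambiguous"
    if (base$label == "ambiguous")
      base$reason <- if (deep) "deep coalescence yet admixture signal"
        else "shallow coalescence without admixture signal"
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- c(depth = depthThreshold,
                               admixture = admixThreshold)
  out
}
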