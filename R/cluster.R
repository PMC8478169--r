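# Detection of the five-role merR-copA core cluster on annotated replicons:
# product-keyword role assignment, run-based neighborhood detection anchored
# on copA, genomic-island overlap, and plasmid/chromosome classification.

CLUSTER_ROLES <- c("merR", "copA", "cupredoxin", "duf2933_hypothetical", "icmt")

#' Default product-keyword rules for the five core-cluster roles
#'
#' Case-insensitive substring matches against the annotated product. The
#' `duf2933_hypothetical` role matches "DUF2933" directly; a bare
#' "hypothetical protein" earns the role only contextually, when its
#' immediate role-bearing neighbours are the cupredoxin and the
#' isoprenylcysteine carboxylmethyltransferase (in either order), which keeps
#' genome-wide hypothetical proteins out of the role set.
#'
#' @return Named list of keyword character vectors, one per role.
#' @export
default_role_rules <- function() {
  list(merR = c("merr"),
       copA = c("copper-translocating p-type atpase", "cation transport atpase"),
       cupredoxin = c("cupredoxin", "plastocyanin"),
       duf2933_hypothetical = c("duf2933"),
       icmt = c("isoprenylcysteine"))
}

#' Assign core-cluster roles to gene features by product keywords
#'
#' @param features `data.frame(feature_id, replicon_id, start, end, strand,
#'   product)`, 1-based inclusive coordinates.
#' @param role_rules See [default_role_rules].
#' @return `features` with a `role` column (one of the five roles or
#'   `"none"`). A product matching two or more roles is an error (ambiguous
#'   rules).
#' @export
assign_roles <- function(features, role_rules = default_role_rules()) {
  stopifnot(all(c("feature_id", "replicon_id", "start", "end", "product")
                %in% names(features)))
  prod <- tolower(features$product)
  hit_mat <- vapply(role_rules, function(kws) {
    Reduce(`|`, lapply(kws, function(k) grepl(k, prod, fixed = TRUE)))
  }, logical(nrow(features)))
  if (nrow(features) == 1L) hit_mat <- matrix(hit_mat, nrow = 1,
                                              dimnames = list(NULL, names(role_rules)))
  n_roles <- rowSums(hit_mat)
  if (any(n_roles > 1L)) {
    off <- which(n_roles > 1L)[1]
    stop(sprintf("ambiguous role rules: product '%s' (%s) matches roles %s",
                 features$product[off], features$feature_id[off],
                 paste(colnames(hit_mat)[hit_mat[off, ]], collapse = ", ")))
  }
  role <- rep("none", nrow(features))
  for (r in colnames(hit_mat)) role[hit_mat[, r]] <- r
  features$role <- role
  # contextual rule: bare "hypothetical protein" between cupredoxin and icmt
  hypo <- role == "none" & grepl("hypothetical protein", prod, fixed = TRUE)
  if (any(hypo)) {
    for (rep_id in unique(features$replicon_id[hypo])) {
      sel <- which(features$replicon_id == rep_id)
      sel <- sel[order(features$start[sel])]
      for (j in seq_along(sel)) {
        i <- sel[j]
        if (!hypo[i]) next
        nb <- c(if (j > 1) features$role[sel[j - 1]] else NA,
                if (j < length(sel)) features$role[sel[j + 1]] else NA)
        if (setequal(nb[!is.na(nb)], c("cupredoxin", "icmt")) &&
            length(nb[!is.na(nb)]) == 2L)
          features$role[i] <- "duf2933_hypothetical"
      }
    }
  }
  features
}

#' Detect merR-copA core clusters on one replicon
#'
#' Scans role-assigned genes in coordinate order and forms maximal runs of
#' role-bearing genes in which at most `max_intervening` consecutive
#' role-less genes are tolerated. A run is called as a cluster when it
#' contains the copA anchor and at least `min_roles` distinct roles;
#' completeness is `"full"` iff all five roles are present. A run with
#' several copA genes yields one call anchored at the first.
#'
#' @param features Role-assigned features of a single replicon, sorted by
#'   `start` (unsorted input is an error).
#' @param max_intervening Maximum run of role-less genes tolerated inside a
#'   cluster. Default 1.
#' @param min_roles Minimum number of distinct roles. Default 3.
#' @return A `data.frame` of calls: `replicon_id`, `anchor_copA`,
#'   `completeness`, `n_roles`, `start`, `end`, plus list-columns `members`
#'   (per-call data frame of the role-bearing member genes in order) and
#'   `missing_roles`. Columns `replicon_class` and `on_genomic_island` are
#'   initialised `NA` for [annotate_gi_overlap].
#' @export
detect_core_clusters <- function(features, max_intervening = 1L,
                                 min_roles = 3L) {
  if (!"role" %in% names(features))
    stop("features must carry roles; run assign_roles() first")
  if (length(unique(features$replicon_id)) > 1L)
    stop("detect_core_clusters works on one replicon at a time")
  if (is.unsorted(features$start))
    stop("features must be sorted by start coordinate")
  rows <- list()
  idx_role <- which(features$role != "none")
  if (length(idx_role)) {
    # split role-bearing genes into runs: a gap of > max_intervening
    # role-less genes between consecutive role genes breaks the run
    gaps <- diff(idx_role) - 1L
    run_id <- cumsum(c(0L, gaps > max_intervening))
    for (run in split(idx_role, run_id)) {
      memb <- features[run, , drop = FALSE]
      roles <- unique(memb$role)
      if (!"copA" %in% roles || length(roles) < min_roles) next
      anchor <- memb$feature_id[memb$role == "copA"][1]
      rows[[length(rows) + 1L]] <- data.frame(
        replicon_id = memb$replicon_id[1],
        anchor_copA = anchor,
        completeness = if (length(roles) == length(CLUSTER_ROLES)) "full" else "partial",
        n_roles = length(roles),
        start = min(memb$start), end = max(memb$end),
        members = I(list(memb)),
        missing_roles = I(list(setdiff(CLUSTER_ROLES, roles))),
        replicon_class = NA_character_,
        on_genomic_island = NA,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(replicon_id = character(), anchor_copA = character(),
                      completeness = character(), n_roles = integer(),
                      start = integer(), end = integer(),
                      members = I(list()), missing_roles = I(list()),
                      replicon_class = character(), on_genomic_island = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect core clusters across all replicons of an annotated genome
#'
#' @param features Role-assigned features, any number of replicons.
#' @inheritParams detect_core_clusters
#' @return Row-bound calls from [detect_core_clusters] per replicon.
#' @export
detect_core_clusters_all <- function(features, max_intervening = 1L,
                                     min_roles = 3L) {
  calls <- lapply(split(features, features$replicon_id), function(f) {
    f <- f[order(f$start), , drop = FALSE]
    detect_core_clusters(f, max_intervening, min_roles)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Annotate cluster calls with genomic-island overlap and replicon class
#'
#' A call is on a genomic island iff the midpoint of every member gene falls
#' inside some island interval on its replicon (strict all-members rule); a
#' lenient mode flags any overlap of the cluster span with an island.
#'
#' @param calls Cluster calls from [detect_core_clusters].
#' @param gi_intervals `data.frame(replicon_id, start, end)` in 0-based
#'   half-open (BED) coordinates, e.g. from [read_gi_intervals]. Intervals on
#'   replicons absent from the calls produce a warning and are ignored.
#' @param replicon_manifest `data.frame(replicon_id, class)` with class
#'   `"chromosome"` or `"plasmid"`.
#' @param mode `"all_members"` (default, strict) or `"any_overlap"`.
#' @return `calls` with `on_genomic_island` and `replicon_class` filled in.
#' @export
annotate_gi_overlap <- function(calls, gi_intervals, replicon_manifest,
                                mode = c("all_members", "any_overlap")) {
  mode <- match.arg(mode)
  if (nrow(calls) == 0L) return(calls)
  known <- unique(calls$replicon_id)
  if (nrow(gi_intervals)) {
    unk <- setdiff(unique(gi_intervals$replicon_id), known)
    if (length(unk)) {
      warning("genomic-island intervals on unknown replicon(s) ignored: ",
              paste(unk, collapse = ", "))
      gi_intervals <- gi_intervals[!gi_intervals$replicon_id %in% unk, , drop = FALSE]
    }
  }
  covered <- function(rep_id, pos) {
    # pos 1-based; BED interval [start, end) covers 1-based (start+1)..end
    gi <- gi_intervals[gi_intervals$replicon_id == rep_id, , drop = FALSE]
    if (nrow(gi) == 0L) return(rep(FALSE, length(pos)))
    vapply(pos, function(p) any(p > gi$start & p <= gi$end), logical(1))
  }
  for (i in seq_len(nrow(calls))) {
    rep_id <- calls$replicon_id[i]
    if (mode == "all_members") {
      memb <- calls$members[[i]]
      mids <- floor((memb$start + memb$end) / 2)
      calls$on_genomic_island[i] <- all(covered(rep_id, mids))
    } else {
      gi <- gi_intervals[gi_intervals$replicon_id == rep_id, , drop = FALSE]
      calls$on_genomic_island[i] <-
        nrow(gi) > 0 && any(gi$start < calls$end[i] & gi$end >= calls$start[i])
    }
    m <- match(rep_id, replicon_manifest$replicon_id)
    calls$replicon_class[i] <-
      if (is.na(m)) NA_character_ else replicon_manifest$class[m]
  }
  calls
}

#' Read gene features from a GFF3 file
#'
#' Imports CDS/gene records via rtracklayer and returns the flat feature
#' table the cluster detector consumes (1-based inclusive coordinates).
#'
#' @param path GFF3 path.
#' @param feature_type Feature type(s) to keep. Default `"CDS"`.
#' @return `data.frame(feature_id, replicon_id, start, end, strand, product)`.
#' @export
read_gene_features <- function(path, feature_type = "CDS") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  md <- S4Vectors::mcols(gr)
  id <- if ("locus_tag" %in% names(md)) as.character(md$locus_tag)
        else as.character(md$ID)
  prod <- if ("product" %in% names(md)) as.character(md$product)
          else rep(NA_character_, length(gr))
  df <- data.frame(feature_id = id,
                   replicon_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   product = prod, stringsAsFactors = FALSE)
  df[order(df$replicon_id, df$start), , drop = FALSE]
}

#' Read genomic-island intervals from a BED file
#'
#' Returned coordinates are 0-based half-open, as in the file.
#'
#' @param path BED path.
#' @return `data.frame(replicon_id, start, end)`.
#' @export
read_gi_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(replicon_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a replicon manifest config (tab-delimited: replicon_id, class)
#'
#' @param path File path.
#' @return `data.frame(replicon_id, class)`.
#' @export
read_replicon_manifest <- function(path) {
  mf <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("replicon_id", "class") %in% names(mf)))
  bad <- setdiff(unique(mf$class), c("chromosome", "plasmid"))
  if (length(bad)) stop("replicon class must be chromosome or plasmid, got: ",
                        paste(bad, collapse = ", "))
  mf
}

#' Flatten cluster calls to a delimited-friendly table
#'
#' One row per call with member locus tags and roles collapsed into strings,
#' mirroring a presence/organization table (replicon, loci, completeness,
#' on-GI flag, plasmid flag).
#'
#' @param calls Annotated calls from [annotate_gi_overlap].
#' @return A flat `data.frame`.
#' @export
flatten_cluster_calls <- function(calls) {
  data.frame(
    replicon_id = calls$replicon_id,
    replicon_class = calls$replicon_class,
    anchor_copA = calls$anchor_copA,
    completeness = calls$completeness,
    n_roles = calls$n_roles,
    start = calls$start, end = calls$end,
    on_genomic_island = calls$on_genomic_island,
    members = vapply(calls$members, function(m)
      paste(m$feature_id, collapse = ";"), character(1)),
    roles = vapply(calls$members, function(m)
      paste(m$role, collapse = ";"), character(1)),
    missing_roles = vapply(calls$missing_roles, function(r)
      if (length(r)) paste(r, collapse = ";") else "", character(1)),
    stringsAsFactors = FALSE)
}
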