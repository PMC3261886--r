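#' Evolve a nucleotide alignment along a gene tree
#'
#' Simulates sequences of `profile$length` base pairs under HKY85 with
#' discrete-Gamma rate heterogeneity along the branches of a gene tree.
#' The root sequence is drawn uniformly over {A,C,G,T} per site; each
#' site is independently assigned one of the equal-probability Gamma rate
#' categories; every branch then applies the closed-form transition
#' probabilities for distance `branch_length * site_rate`.  Branch
#' lengths are taken on the locus substitution scale (nuclear-scale ages
#' times the locus rate multiplier).
#'
#' @param gt A `gene_tree` (or an `ape::phylo` with branch lengths in
#'   expected substitutions/site).
#' @param profile A [marker_profile()]; defaults to the gene tree's own.
#' @param rng_seed Optional integer seed for a deterministic draw.
#' @return A `locus_alignment`: integer matrix `mat` (tips x sites,
#'   values 1..4 = A,G,C,T), `labels`, `profile`.
#' @export
evolve_alignment <- function(gt, profile = NULL, rng_seed = NULL) {
  if (inherits(gt, "gene_tree")) {
    if (is.null(profile)) profile <- gt$profile
    parent <- gt$parent
    len <- numeric(length(parent))
    nz <- parent != 0
    len[nz] <- (gt$ages[parent[nz]] - gt$ages[which(nz)]) *
      profile$rate_multiplier
    ntip <- gt$ntip
    labels <- gt$tip_labels
    nnode <- length(parent)
  } else if (inherits(gt, "phylo")) {
    if (is.null(profile)) stop("profile is required for a raw phylo")
    ntip <- length(gt$tip.label)
    nnode <- ntip + gt$Nnode
    parent <- integer(nnode)
    len <- numeric(nnode)
    parent[gt$edge[, 2]] <- gt$edge[, 1]
    len[gt$edge[, 2]] <- gt$edge.length
    labels <- gt$tip.label
  } else stop("gt must be a gene_tree or phylo")
  if (any(len < 0)) stop("negative branch length")
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed %% .Machine$integer.max))

  L <- profile$length
  rates <- discrete_gamma_rates(profile$gamma_shape, profile$n_categories)
  cat_of_site <- sample.int(length(rates), L, replace = TRUE)

  states <- matrix(0L, nnode, L)
  root <- which(parent == 0)
  states[root, ] <- sample.int(4L, L, replace = TRUE)

  ord <- preorder_nodes(parent, root)
  for (v in ord) {
    d <- len[v]
    ps <- states[parent[v], ]
    if (d == 0) { states[v, ] <- ps; next }
    cs <- integer(L)
    for (k in seq_along(rates)) {
      pr <- hky_probs(d * rates[k], profile$kappa)
      for (s in 1:4) {
        idx <- which(cat_of_site == k & ps == s)
        if (!length(idx)) next
        prob <- rep(pr$tv, 4)
        prob[s] <- pr$same
        prob[ts_partner[s]] <- pr$ts
        cs[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = prob)
      }
    }
    states[v, ] <- cs
  }
  mat <- states[seq_len(ntip), , drop = FALSE]
  rownames(mat) <- labels
  structure(list(mat = mat, labels = labels, profile = profile),
            class = "locus_alignment")
}

preorder_nodes <- function(parent, root) {
  nnode <- length(parent)
  out <- integer(0)
  frontier <- root
  remaining <- setdiff(seq_len(nnode), root)
  while (length(remaining)) {
    nxt <- remaining[parent[remaining] %in% frontier]
    if (!length(nxt)) stop("malformed tree: unreachable nodes")
    out <- c(out, nxt)
    frontier <- c(frontier, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  out
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %d sequences x %d bp (%s)\n",
              nrow(x$mat), ncol(x$mat), x$profile$marker_class))
  invisible(x)
}

#' Alignment text export
#'
#' Writers for the two plain-text formats consumed downstream: FASTA and
#' relaxed (sequential) PHYLIP.  `concat_alignments()` concatenates loci
#' over a shared label set and records partition boundaries.
#'
#' @param aln A `locus_alignment`.
#' @param file Output path.
#' @export
write_alignment_fasta <- function(aln, file) {
  ch <- matrix(NUC[aln$mat], nrow(aln$mat))
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ch)))
    writeLines(c(paste0(">", aln$labels[i]),
                 paste(ch[i, ], collapse = "")), con)
  invisible(file)
}

#' @rdname write_alignment_fasta
#' @export
write_alignment_phylip <- function(aln, file) {
  ch <- matrix(NUC[aln$mat], nrow(aln$mat))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", nrow(ch), ncol(ch)), con)
  for (i in seq_len(nrow(ch)))
    writeLines(paste(format(aln$labels[i], width = 12),
                     paste(ch[i, ], collapse = "")), con)
  invisible(file)
}

#' @rdname write_alignment_fasta
#' @param file Path to a FASTA file written by [write_alignment_fasta()].
#' @param profile Marker profile to attach.
#' @export
read_alignment_fasta <- function(file, profile = nuclear_profile()) {
  dna <- ape::read.dna(file, format = "fasta", as.character = TRUE)
  mat <- matrix(match(tolower(dna), NUC), nrow(dna),
                dimnames = list(rownames(dna), NULL))
  structure(list(mat = mat, labels = rownames(dna), profile = profile),
            class = "locus_alignment")
}

#' @rdname write_alignment_fasta
#' @param alns List of `locus_alignment` objects sharing tip labels.
#' @return `concat_alignments()`: a list with the combined matrix and a
#'   `partitions` data frame (locus, start, end).
#' @export
concat_alignments <- function(alns) {
  labels <- alns[[1]]$labels
  mats <- lapply(alns, function(a) a$mat[labels, , drop = FALSE])
  lens <- vapply(mats, ncol, integer(1))
  ends <- cumsum(lens)
  list(mat = do.call(cbind, mats), labels = labels,
       partitions = data.frame(locus = seq_along(alns),
                               start = c(1L, utils::head(ends, -1) + 1L),
                               end = ends))
}
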