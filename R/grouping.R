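#' Group proteins by sequence identity
#'
#' Collapses database proteins into groups inferred and quantified as a unit.
#' Microbial proteins are grouped at 100% identity (classes of byte-identical
#' sequences, which also merges identical proteins shared across related
#' strains). Human proteins are grouped at 90% identity by greedy centroid
#' clustering: sequences are visited by decreasing length (ties broken by
#' accession), and each joins the first existing centroid whose global
#' alignment identity — matches divided by alignment length, gaps included —
#' reaches the threshold, otherwise it founds a new centroid.
#'
#' @param database named character vector of protein sequences (or an
#'   `AAStringSet`); decoy entries are not expected here.
#' @param binMap named character vector accession -> bin id, with human
#'   proteins mapped to `"human"`.
#' @param humanThreshold identity threshold for human proteins (default 0.90).
#' @param microbialThreshold identity threshold for microbial proteins
#'   (default 1.00, i.e. byte-identical classes; lower values fall back to the
#'   same greedy centroid clustering as for human proteins).
#' @return list with:
#'   \describe{
#'     \item{assignment}{named character vector accession -> group id;}
#'     \item{groups}{data.frame per group: `group_id`, `origin`,
#'       `representative`, `members` (";"-separated), `n_members`,
#'       `identity_threshold`.}
#'   }
#' @export
groupProteinsByIdentity <- function(database, binMap, humanThreshold = 0.90,
                                    microbialThreshold = 1.00) {
  if (is(database, "AAStringSet"))
    database <- setNames(as.character(database), names(database))
  stopifnot(is.character(database), !is.null(names(database)))
  humanThreshold <- assertFraction(humanThreshold, "humanThreshold", 0, 1)
  microbialThreshold <- assertFraction(microbialThreshold,
                                       "microbialThreshold", 0, 1)
  missing <- setdiff(names(database), names(binMap))
  if (length(missing))
    stop("accession(s) missing from bin map: ",
         paste(utils::head(missing, 5), collapse = ", "))

  origin <- ifelse(binMap[names(database)] == "human", "human", "microbial")
  assignment <- character(0)
  groups <- NULL

  clusterSet <- function(seqs, threshold, prefix) {
    if (!length(seqs)) return(NULL)
    if (threshold >= 1) {
      cls <- match(seqs, unique(seqs))
      members <- split(names(seqs), cls)
    } else {
      ord <- order(-nchar(seqs), names(seqs))
      centroids <- integer(0)          # indices into ord'd seqs
      memberOf <- integer(length(seqs))
      sq <- seqs[ord]
      for (i in seq_along(sq)) {
        hit <- 0L
        for (ci in seq_along(centroids)) {
          if (alignmentIdentity(sq[[centroids[ci]]], sq[[i]]) >= threshold) {
            hit <- ci; break
          }
        }
        if (!hit) { centroids <- c(centroids, i); hit <- length(centroids) }
        memberOf[i] <- hit
      }
      members <- split(names(sq), memberOf)
    }
    # deterministic group order: by smallest member accession
    members <- members[order(vapply(members, min, character(1)))]
    members
  }

  makeGroups <- function(members, origin, prefix, threshold) {
    if (is.null(members) || !length(members)) return(NULL)
    ids <- sprintf("%s%05d", prefix, seq_along(members))
    for (i in seq_along(members))
      assignment[members[[i]]] <<- ids[i]
    reps <- vapply(members, function(m) {
      # representative: longest member, ties by accession
      m[order(-nchar(database[m]), m)][1]
    }, character(1))
    data.frame(group_id = ids, origin = origin, representative = unname(reps),
               members = vapply(members, paste, character(1), collapse = ";"),
               n_members = lengths(members), identity_threshold = threshold,
               row.names = NULL, stringsAsFactors = FALSE)
  }

  groups <- rbind(
    makeGroups(clusterSet(database[origin == "microbial"],
                          microbialThreshold, "MG"),
               "microbial", "MG", microbialThreshold),
    makeGroups(clusterSet(database[origin == "human"],
                          humanThreshold, "HG"),
               "human", "HG", humanThreshold))
  list(assignment = assignment, groups = groups)
}

# global alignment identity: matches / alignment length (gaps included);
# match +1, mismatch -1, affine gaps at Biostrings defaults
alignmentIdentity <- function(a, b) {
  if (a == b) return(1)
  sub <- .aaSubstitutionMatrix()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = sub)
  alnLen <- nchar(as.character(Biostrings::pattern(aln)))
  Biostrings::nmatch(aln) / alnLen
}

.aaSubCache <- new.env(parent = emptyenv())
.aaSubstitutionMatrix <- function() {
  if (is.null(.aaSubCache$m)) {
    alph <- c(.AA_EXTENDED, "*")
    m <- matrix(-1, length(alph), length(alph),
                dimnames = list(alph, alph))
    diag(m) <- 1
    .aaSubCache$m <- m
  }
  .aaSubCache$m
}
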