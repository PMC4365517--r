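#' Construct a pedigree
#'
#' Parentage records with unknown parents coded as `0`, `NA` or `""`. Parents
#' that are named but have no record of their own are auto-added as founders.
#'
#' @param id,sire,dam vectors of identifiers (coerced to character).
#' @param birth_year optional integer vector.
#' @return Object of class `pedigree`: a data frame with columns `id`, `sire`,
#'   `dam` (`NA` = unknown) and optionally `birth_year`, in an order where
#'   auto-added founders precede the original records.
#' @export
pedigree <- function(id, sire, dam, birth_year = NULL) {
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA") | is.na(x)] <- NA
    x
  }
  id <- as.character(id); sire <- norm(sire); dam <- norm(dam)
  if (anyNA(id) || any(id %in% c("0", "")))
    stop("individual ids must be non-missing and not '0'")
  if (anyDuplicated(id)) stop("duplicate individual id: ", id[duplicated(id)][1])
  selfp <- which(id == sire | id == dam)
  if (length(selfp)) stop("individual is its own parent: ", id[selfp[1]])
  named_parents <- setdiff(unique(c(sire, dam)), c(id, NA))
  if (length(named_parents)) {
    message(length(named_parents), " named parent(s) auto-added as founders")
    id <- c(named_parents, id)
    sire <- c(rep(NA_character_, length(named_parents)), sire)
    dam <- c(rep(NA_character_, length(named_parents)), dam)
    if (!is.null(birth_year))
      birth_year <- c(rep(NA_integer_, length(named_parents)), birth_year)
  }
  ped <- data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
  if (!is.null(birth_year)) ped$birth_year <- as.integer(birth_year)
  class(ped) <- c("pedigree", "data.frame")
  topological_order(ped) # validates acyclicity
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("pedigree: %d individuals (%d founders)\n", nrow(x), founders))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Read a pedigree from a delimited file
#'
#' Expects at least three columns: id, sire, dam, optionally birth year.
#' Unknown parents are coded `0` or empty. A header row is detected when the
#' first field of the first line is `id` (case-insensitive).
#'
#' @param path file path.
#' @param sep field separator; default `""` splits on any whitespace, use
#'   `","` for CSV.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path, sep = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1),
                    if (sep == "") "[ \t]+" else sep)[[1]]
  header <- length(first) && tolower(first[1]) == "id"
  tab <- utils::read.table(path, header = header, sep = sep,
                           colClasses = "character", fill = TRUE)
  if (ncol(tab) < 3) stop("pedigree file needs at least 3 columns (id, sire, dam)")
  by <- if (ncol(tab) >= 4) suppressWarnings(as.integer(tab[[4]])) else NULL
  pedigree(tab[[1]], tab[[2]], tab[[3]], birth_year = by)
}

#' Topological ordering of a pedigree
#'
#' Every parent precedes all of its offspring; ties are broken by input order
#' (Kahn's algorithm with a FIFO over the original record order).
#'
#' @param ped a [pedigree()] or data frame with columns id, sire, dam.
#' @return Character vector of ids in topological order.
#' @export
topological_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (x in seq_len(n)) {
    for (p in c(si[x], di[x])) if (p > 0L) {
      indeg[x] <- indeg[x] + 1L
      children[[p]] <- c(children[[p]], x)
    }
  }
  out <- integer(0)
  ready <- which(indeg == 0L) # ascending = input order
  while (length(ready)) {
    x <- ready[1]; ready <- ready[-1]
    out <- c(out, x)
    for (ch in children[[x]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- sort(c(ready, ch))
    }
  }
  if (length(out) < n) {
    left <- setdiff(seq_len(n), out)
    stop("pedigree contains a cycle involving '", ped$id[left[1]], "'")
  }
  ped$id[out]
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Tabular method over the whole pedigree in topological order:
#' `A[x, y] = (A[sire(x), y] + A[dam(x), y]) / 2` for `y` ordered before `x`,
#' `A[x, x] = 1 + A[sire(x), dam(x)] / 2`, with unknown parents contributing 0
#' (founders assumed unrelated and non-inbred).
#'
#' @param ped a [pedigree()].
#' @param ids optional subset of ids for the returned matrix (default all).
#' @return A [rel_matrix()] with method `"A_ped"`.
#' @export
a_matrix <- function(ped, ids = NULL) {
  ord <- topological_order(ped)
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ord
  rec <- pos[ped$id] # input record -> topological position
  si <- rep(0L, n); di <- rep(0L, n)
  si[rec] <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di[rec] <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  for (x in seq_len(n)) {
    s <- si[x]; d <- di[x]
    if (x > 1L) {
      ys <- seq_len(x - 1L)
      row <- numeric(x - 1L)
      if (s > 0L) row <- row + A[s, ys]
      if (d > 0L) row <- row + A[d, ys]
      A[x, ys] <- A[ys, x] <- row / 2
    }
    A[x, x] <- 1 + if (s > 0L && d > 0L) A[s, d] / 2 else 0
  }
  if (is.null(ids)) ids <- ped$id
  missing_ids <- setdiff(ids, ped$id)
  if (length(missing_ids)) stop("id(s) not in pedigree: ",
                                paste(utils::head(missing_ids, 5), collapse = ", "))
  rel_matrix(A[ids, ids, drop = FALSE], method = "A_ped")
}

#' Pedigree inbreeding coefficients
#'
#' Wright's inbreeding coefficient `F(x) = kinship(sire(x), dam(x))` via a
#' memoised kinship recursion over the pedigree, without materialising the
#' full relationship matrix. Identical (to machine precision) to
#' `diag(a_matrix(ped)) - 1`.
#'
#' @param ped a [pedigree()].
#' @return Data frame of class `inbreeding_table` with columns `id`, `F`.
#' @export
pedigree_inbreeding <- function(ped) {
  ord <- topological_order(ped)
  n <- nrow(ped)
  pos <- seq_len(n); names(pos) <- ord
  si <- di <- rep(0L, n)
  si[pos[ped$id]] <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di[pos[ped$id]] <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  Fc <- numeric(n) # inbreeding per topological position
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  kin <- function(a, b) {
    if (a == 0L || b == 0L) return(0)
    if (a == b) return(0.5 * (1 + Fc[a]))
    if (a < b) { t <- a; a <- b; b <- t } # a is topologically later
    key <- paste0(a, ":", b)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- 0.5 * (kin(si[a], b) + kin(di[a], b))
    memo[[key]] <- val
    val
  }
  for (x in seq_len(n)) Fc[x] <- kin(si[x], di[x])
  structure(data.frame(id = ped$id, F = Fc[pos[ped$id]],
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("inbreeding_table", "data.frame"))
}

#' Number of complete ancestral generations
#'
#' Largest `g` such that every one of the `2^k` ancestor slots is filled for
#' all generations `k <= g`; 0 if a parent is unknown. A single missing
#' grandparent caps the depth at 1 regardless of the other lineage.
#'
#' @param ped a [pedigree()].
#' @param id individual id (vectorised).
#' @param max_depth search cap (default 30).
#' @return Integer vector of depths.
#' @export
complete_generations <- function(ped, id, max_depth = 30L) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  unknown <- setdiff(id, ped$id)
  if (length(unknown)) stop("id(s) not in pedigree: ", unknown[1])
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  one <- function(i) {
    slots <- idx[[i]]
    depth <- 0L
    while (depth < max_depth) {
      parents <- c(si[slots], di[slots])
      if (any(parents == 0L)) break
      depth <- depth + 1L
      slots <- parents
    }
    depth
  }
  vapply(id, one, integer(1))
}

#' Nested pedigree-depth groups
#'
#' For each threshold `t`, the group of individuals whose number of complete
#' ancestral generations is at least `t`; groups are nested by construction.
#'
#' @param ped a [pedigree()].
#' @param ids individuals to group (default: all in `ped`).
#' @param thresholds ascending integer thresholds (default `c(1, 2, 4)`).
#' @return Named list (`depth<t>`) of id vectors.
#' @export
depth_groups <- function(ped, ids = ped$id, thresholds = c(1L, 2L, 4L)) {
  thresholds <- as.integer(thresholds)
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  cg <- complete_generations(ped, ids)
  out <- lapply(thresholds, function(t) ids[cg >= t])
  names(out) <- paste0("depth", thresholds)
  out
}
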