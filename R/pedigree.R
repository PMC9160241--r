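# Pedigree handling: validation and topological ordering, pruning to
# phenotyped animals plus n generations of ancestors, inbreeding
# coefficients, genetic (unknown-parent) groups, and the sparse inverse of
# the numerator relationship matrix built directly from pedigree rules.

#' Validate and topologically order a pedigree
#'
#' A pedigree is a data frame with columns `animal`, `sire`, `dam` (0 =
#' unknown parent), and optionally `sex` and `birth_year`. The result is
#' ordered so parents precede offspring; self-parenting or cycles are
#' errors.
#'
#' @param ped pedigree data frame.
#' @return the ordered pedigree tibble.
#' @export
as_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$animal)) stop("duplicate animal ids", call. = FALSE)
  if (any(ped$animal == 0)) stop("animal id 0 is reserved for unknown parents",
                                 call. = FALSE)
  known <- c(0, ped$animal)
  if (!all(ped$sire %in% known) || !all(ped$dam %in% known)) {
    stop("sire/dam ids not present in pedigree", call. = FALSE)
  }
  if (any(ped$sire == ped$animal | ped$dam == ped$animal)) {
    stop("self-parenting detected", call. = FALSE)
  }
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- ifelse(ped$sire == 0, 0L, idx[as.character(ped$sire)])
  di <- ifelse(ped$dam == 0, 0L, idx[as.character(ped$dam)])
  if (all(si < seq_len(n)) && all(di < seq_len(n))) {
    return(ped) # already topologically ordered; keep input order
  }
  # Kahn topological sort in waves
  placed <- logical(n)
  order_out <- integer(n)
  k <- 0L
  repeat {
    ready <- which(!placed &
                     (si == 0L | placed[pmax(si, 1L)]) &
                     (di == 0L | placed[pmax(di, 1L)]))
    if (!length(ready)) break
    order_out[k + seq_along(ready)] <- ready
    k <- k + length(ready)
    placed[ready] <- TRUE
  }
  if (k < n) stop("pedigree contains a cycle", call. = FALSE)
  ped[order_out, ]
}

ped_indices <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  list(
    sire = ifelse(ped$sire == 0, 0L,
                  unname(idx[as.character(ped$sire)])),
    dam = ifelse(ped$dam == 0, 0L,
                 unname(idx[as.character(ped$dam)]))
  )
}

#' Prune a pedigree to phenotyped animals and their ancestors
#'
#' Keeps the phenotyped animals plus ancestors up to `n_generations` back
#' (0 keeps only the phenotyped animals themselves). Parents that fall
#' outside the kept set become unknown.
#'
#' @param ped pedigree (see [as_pedigree()]).
#' @param phenotyped_ids animal ids with phenotypes; must exist in `ped`.
#' @param n_generations generations of ancestors to retain.
#' @return the pruned, re-ordered pedigree tibble.
#' @export
prune_pedigree <- function(ped, phenotyped_ids, n_generations = 5L) {
  ped <- as_pedigree(ped)
  if (!all(phenotyped_ids %in% ped$animal)) {
    stop("unknown phenotyped ids: ",
         paste(utils::head(setdiff(phenotyped_ids, ped$animal), 5L),
               collapse = ", "), call. = FALSE)
  }
  parent_of <- ped[c("animal", "sire", "dam")]
  keep <- unique(phenotyped_ids)
  frontier <- keep
  g <- 0L
  while (g < n_generations && length(frontier)) {
    rows <- parent_of[parent_of$animal %in% frontier, ]
    parents <- setdiff(unique(c(rows$sire, rows$dam)), c(0, keep))
    keep <- c(keep, parents)
    frontier <- parents
    g <- g + 1L
  }
  out <- ped[ped$animal %in% keep, ]
  out$sire[!out$sire %in% keep] <- 0L
  out$dam[!out$dam %in% keep] <- 0L
  as_pedigree(out)
}

#' Inbreeding coefficients
#'
#' Meuwissen-Luo style recursive computation; founders (and animals with an
#' unknown parent) have F = 0.
#'
#' @param ped pedigree (see [as_pedigree()]).
#' @return numeric vector of inbreeding coefficients, one per pedigree row,
#'   with the per-animal Mendelian-sampling variance scale in attribute
#'   `"D"`.
#' @export
inbreeding_coefficients <- function(ped) {
  ped <- as_pedigree(ped)
  pi <- ped_indices(ped)
  f <- cpp_inbreeding(as.integer(pi$sire), as.integer(pi$dam))
  names(f) <- ped$animal
  f
}

#' Genetic (unknown-parent) groups
#'
#' Founders are grouped within sex by birth year: years are merged greedily
#' in ascending order until every group contains at least `min_size`
#' founders; a trailing undersized group merges backwards. Every unknown
#' parent slot maps to a group: a founder's unknown sire and dam map to the
#' founder's own group; an unknown parent of a non-founder maps to the group
#' of the matching sex stratum whose year span is nearest the animal's birth
#' year.
#'
#' @param ped pedigree with `sex` and `birth_year` columns.
#' @param min_size minimum founders per group.
#' @return a `genetic_groups` object: `groups` tibble (group_id, sex,
#'   year_min, year_max, n_members) and `slots` tibble (animal, slot,
#'   group_id).
#' @export
assign_genetic_groups <- function(ped, min_size = 50L) {
  ped <- as_pedigree(ped)
  stopifnot(all(c("sex", "birth_year") %in% names(ped)))
  founder <- ped$sire == 0 & ped$dam == 0
  groups <- list()
  gid <- 0L
  for (sx in sort(unique(ped$sex[founder]))) {
    yrs <- sort(unique(ped$birth_year[founder & ped$sex == sx]))
    counts <- vapply(yrs, function(y) sum(founder & ped$sex == sx &
                                            ped$birth_year == y), integer(1))
    if (sum(counts) < min_size) {
      warning("sex stratum '", sx, "' has fewer than ", min_size,
              " founders in total; a single group is used", call. = FALSE)
      gid <- gid + 1L
      groups[[gid]] <- tibble::tibble(group_id = gid, sex = sx,
                                      year_min = min(yrs), year_max = max(yrs),
                                      n_members = sum(counts))
      next
    }
    start <- 1L; acc <- 0L
    spans <- list()
    for (k in seq_along(yrs)) {
      acc <- acc + counts[k]
      if (acc >= min_size || k == length(yrs)) {
        spans[[length(spans) + 1L]] <- c(start, k, acc)
        start <- k + 1L; acc <- 0L
      }
    }
    # trailing undersized group merges backwards
    if (length(spans) > 1L) {
      last <- spans[[length(spans)]]
      if (last[3] < min_size) {
        prev <- spans[[length(spans) - 1L]]
        spans[[length(spans) - 1L]] <- c(prev[1], last[2], prev[3] + last[3])
        spans[[length(spans)]] <- NULL
      }
    }
    for (sp in spans) {
      gid <- gid + 1L
      groups[[gid]] <- tibble::tibble(group_id = gid, sex = sx,
                                      year_min = yrs[sp[1]],
                                      year_max = yrs[sp[2]],
                                      n_members = sp[3])
    }
  }
  groups <- dplyr::bind_rows(groups)

  group_for <- function(sx, year) {
    g <- groups[groups$sex == sx, ]
    if (!nrow(g)) g <- groups # degenerate single-sex pedigree
    hit <- g$group_id[year >= g$year_min & year <= g$year_max]
    if (length(hit)) return(hit[1])
    g$group_id[which.min(pmin(abs(g$year_min - year), abs(g$year_max - year)))]
  }
  sexes <- sort(unique(ped$sex[founder]))
  sire_sex <- if (length(sexes)) sexes[which.max(sexes %in% c("M", "male", "1"))] else "M"
  dam_sex <- setdiff(sexes, sire_sex)[1]
  if (is.na(dam_sex)) dam_sex <- sire_sex
  slots <- list()
  for (r in seq_len(nrow(ped))) {
    if (ped$sire[r] != 0 && ped$dam[r] != 0) next
    is_founder <- founder[r]
    for (slot in c("sire", "dam")) {
      if (ped[[slot]][r] != 0) next
      gidr <- if (is_founder) {
        group_for(ped$sex[r], ped$birth_year[r])
      } else {
        group_for(if (slot == "sire") sire_sex else dam_sex, ped$birth_year[r])
      }
      slots[[length(slots) + 1L]] <- tibble::tibble(
        animal = ped$animal[r], slot = slot, group_id = gidr)
    }
  }
  structure(list(groups = groups, slots = dplyr::bind_rows(slots)),
            class = "genetic_groups")
}

#' @export
print.genetic_groups <- function(x, ...) {
  cat(sprintf("<genetic_groups> %d groups over %d unknown-parent slots\n",
              nrow(x$groups), nrow(x$slots)))
  print(x$groups)
  invisible(x)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from pedigree rules (Henderson's rules with
#' inbreeding, Meuwissen-Luo Mendelian-sampling variances). With
#' `groups`, unknown parents are replaced by their genetic group in the
#' standard unknown-parent-group fashion, augmenting the matrix by one
#' row/column per group.
#'
#' @param ped pedigree (see [as_pedigree()]).
#' @param groups optional `genetic_groups` from [assign_genetic_groups()].
#' @return sparse symmetric matrix (class `dgCMatrix`) of dimension
#'   `n` (or `n + n_groups`), with attributes `log_det_a` (only meaningful
#'   without groups), `D`, and `n_animals`.
#' @export
build_a_inverse <- function(ped, groups = NULL) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  pi <- ped_indices(ped)
  f <- cpp_inbreeding(as.integer(pi$sire), as.integer(pi$dam))
  D <- attr(f, "D")
  ng <- if (is.null(groups)) 0L else nrow(groups$groups)
  sire_col <- pi$sire
  dam_col <- pi$dam
  if (!is.null(groups)) {
    sl <- groups$slots
    key <- paste(sl$animal, sl$slot)
    gmap <- stats::setNames(sl$group_id, key)
    unk_s <- which(sire_col == 0L)
    unk_d <- which(dam_col == 0L)
    sire_col[unk_s] <- n + unname(gmap[paste(ped$animal[unk_s], "sire")])
    dam_col[unk_d] <- n + unname(gmap[paste(ped$animal[unk_d], "dam")])
    if (anyNA(sire_col) || anyNA(dam_col)) {
      stop("groups do not cover every unknown-parent slot", call. = FALSE)
    }
  }
  alpha <- 1 / D
  ks <- sire_col > 0L
  kd <- dam_col > 0L
  kb <- ks & kd
  ii <- c(seq_len(n),
          which(ks), sire_col[ks], which(kd), dam_col[kd],
          sire_col[ks], dam_col[kd],
          sire_col[kb], dam_col[kb])
  jj <- c(seq_len(n),
          sire_col[ks], which(ks), dam_col[kd], which(kd),
          sire_col[ks], dam_col[kd],
          dam_col[kb], sire_col[kb])
  xx <- c(alpha,
          -alpha[ks] / 2, -alpha[ks] / 2, -alpha[kd] / 2, -alpha[kd] / 2,
          alpha[ks] / 4, alpha[kd] / 4,
          alpha[kb] / 4, alpha[kb] / 4)
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n + ng, n + ng))
  attr(m, "log_det_a") <- sum(log(D))
  attr(m, "D") <- D
  attr(m, "F") <- as.numeric(f)
  attr(m, "n_animals") <- n
  m
}
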