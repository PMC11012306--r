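# Domain maps: named, role-tagged residue groups. Every downstream filter
# and classifier (attachment criteria, pose taxonomy, COM distances)
# addresses residues through these groups.

DOMAIN_ROLES <- c("RBD", "HBD", "APT_RBD_BINDER", "APT_HBD_BINDER", "LINKER")

#' Construct a domain map from a residue-level table
#'
#' @param groups data.frame with columns `group`, `chain`, `resseq`, `role`
#' @return object of class `domain_map`
#' @export
new_domain_map <- function(groups) {
  req <- c("group", "chain", "resseq", "role")
  if (!all(req %in% names(groups))) stop("domain map table needs columns: ",
                                         paste(req, collapse = ", "))
  if (!all(groups$role %in% DOMAIN_ROLES))
    stop("unknown role; must be one of ", paste(DOMAIN_ROLES, collapse = ", "))
  key <- paste(groups$chain, groups$resseq)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("domain groups overlap at residue ", dup)
  }
  role_of <- tapply(groups$role, groups$group, function(v) unique(v))
  if (any(lengths(role_of) > 1)) stop("a group must carry a single role")
  structure(list(groups = groups), class = "domain_map")
}

#' @export
print.domain_map <- function(x, ...) {
  g <- x$groups
  tab <- tapply(seq_len(nrow(g)), g$group, length)
  roles <- tapply(g$role, g$group, function(v) v[1])
  cat("<domain_map>\n")
  for (nm in names(tab))
    cat(sprintf("  %-10s role=%-15s %3d residues\n", nm, roles[[nm]], tab[[nm]]))
  invisible(x)
}

#' Bind a domain-map configuration to a structure
#'
#' The configuration names contiguous residue ranges per group, either as an
#' R list `list(HBD1 = list(chain = "A", first = 111, last = 165, role =
#' "HBD"), ...)` or as a path to a YAML/JSON file with the same shape.
#' Every referenced residue must exist in the structure and no residue may
#' fall in two groups.
#'
#' @param s an `apt_structure`
#' @param cfg named list of group specs, or a file path
#' @return a `domain_map`
#' @export
bind_domain_map <- function(s, cfg) {
  if (is.character(cfg) && length(cfg) == 1) {
    cfg <- if (grepl("\\.json$", cfg)) jsonlite::read_json(cfg, simplifyVector = FALSE)
           else yaml::read_yaml(cfg)
  }
  if (!length(cfg) || is.null(names(cfg))) stop("cfg must be a named list of groups")
  res <- residue_table(s)
  have <- paste(res$chain, res$resseq)
  rows <- list()
  for (nm in names(cfg)) {
    g <- cfg[[nm]]
    need <- c("chain", "first", "last", "role")
    if (!all(need %in% names(g))) stop("group ", nm, " lacks chain/first/last/role")
    rs <- seq.int(g$first, g$last)
    want <- paste(g$chain, rs)
    missing <- setdiff(want, have)
    if (length(missing))
      stop("group ", nm, " references absent residue(s): ",
           paste(utils::head(missing, 3), collapse = ", "))
    rows[[nm]] <- data.frame(group = nm, chain = g$chain, resseq = rs,
                             role = g$role, stringsAsFactors = FALSE)
  }
  new_domain_map(do.call(rbind, rows))
}

#' Residues belonging to one or more groups of a domain map
#'
#' @param map a `domain_map`
#' @param group character vector of group names
#' @return data.frame(chain, resseq)
#' @export
map_residues <- function(map, group) {
  g <- map$groups
  unknown <- setdiff(group, unique(g$group))
  if (length(unknown)) stop("unknown group(s): ", paste(unknown, collapse = ", "))
  sel <- g[g$group %in% group, c("chain", "resseq")]
  if (!nrow(sel)) stop("empty group selection")
  sel
}

#' Group names of a domain map, optionally filtered by role
#' @param map a `domain_map`
#' @param role optional role filter
#' @return character vector
#' @export
map_groups <- function(map, role = NULL) {
  g <- map$groups
  if (!is.null(role)) g <- g[g$role %in% role, ]
  sort(unique(g$group))
}
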