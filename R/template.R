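#' Semi-rigid molecular templates
#'
#' A `mol_template` holds a molecule in its own reference frame: atom
#' labels, elements, force-field type keys and Cartesian coordinates
#' (Angstrom), the covalent bond list, and the rotatable groups that make
#' the model semi-rigid.  A rotatable group is an ordered axis bond
#' `(a, b)` plus the set of atoms beyond `b` that rotate about that bond.
#'
#' @param name Template name, e.g. `"NIF"`.
#' @param conformer_id Conformer tag, e.g. `"alpha"`, `"R"`, `"flipped"`.
#' @param atoms `data.frame` with columns `label`, `element`, `type_key`,
#'   `x`, `y`, `z`.
#' @param bonds Two-column character matrix or data.frame of bonded label
#'   pairs.
#' @param groups List of rotatable groups, each
#'   `list(axis = c(a, b), moved = c(...))`.
#' @return A validated object of class `mol_template`.
#' @export
mol_template <- function(name, conformer_id, atoms, bonds, groups = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- matrix(as.character(as.matrix(bonds)), ncol = 2)
  tpl <- structure(list(name = name, conformer_id = conformer_id,
                        atoms = atoms, bonds = bonds, groups = groups),
                   class = "mol_template")
  validate_template(tpl)
  tpl
}

template_xyz <- function(tpl) {
  as.matrix(tpl$atoms[, c("x", "y", "z")])
}

template_adjacency <- function(tpl) {
  labs <- tpl$atoms$label
  adj <- lapply(labs, function(l) character(0))
  names(adj) <- labs
  for (k in seq_len(nrow(tpl$bonds))) {
    a <- tpl$bonds[k, 1]; b <- tpl$bonds[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Connected component containing `start`, optionally with one bond removed.
.component <- function(adj, start, drop_bond = NULL) {
  if (!is.null(drop_bond)) {
    adj[[drop_bond[1]]] <- setdiff(adj[[drop_bond[1]]], drop_bond[2])
    adj[[drop_bond[2]]] <- setdiff(adj[[drop_bond[2]]], drop_bond[1])
  }
  seen <- start
  queue <- start
  while (length(queue)) {
    nxt <- unique(unlist(adj[queue], use.names = FALSE))
    queue <- setdiff(nxt, seen)
    seen <- c(seen, queue)
  }
  seen
}

validate_template <- function(tpl) {
  at <- tpl$atoms
  if (anyDuplicated(at$label)) stop("duplicate atom labels in template ", tpl$name)
  atomic_mass(at$element) # errors on unknown elements
  labs <- at$label
  bad <- setdiff(as.vector(tpl$bonds), labs)
  if (length(bad)) stop("bond references unknown atom(s): ", paste(bad, collapse = ", "))
  xyz <- template_xyz(tpl)
  rownames(xyz) <- labs
  d <- sqrt(rowSums((xyz[tpl$bonds[, 1], , drop = FALSE] -
                     xyz[tpl$bonds[, 2], , drop = FALSE])^2))
  if (any(d < 0.9 | d > 1.9))
    stop("bonded pair outside 0.9-1.9 Angstrom in template ", tpl$name, ": ",
         paste(sprintf("%s-%s (%.2f)", tpl$bonds[d < 0.9 | d > 1.9, 1],
                       tpl$bonds[d < 0.9 | d > 1.9, 2],
                       d[d < 0.9 | d > 1.9]), collapse = ", "))
  adj <- template_adjacency(tpl)
  if (length(.component(adj, labs[1])) != length(labs))
    stop("disconnected bond graph in template ", tpl$name)
  for (g in tpl$groups) {
    if (any(g$moved %in% g$axis))
      stop("rotatable group moved set contains an axis atom")
    comp <- setdiff(.component(adj, g$axis[2], drop_bond = g$axis), g$axis[2])
    if (!setequal(comp, g$moved))
      stop("rotatable group moved-set test failed for axis ",
           paste(g$axis, collapse = "-"))
  }
  invisible(tpl)
}

#' @export
print.mol_template <- function(x, ...) {
  counts <- table(x$atoms$element)
  cat(sprintf("mol_template '%s' (conformer %s): %d atoms [%s], %d bonds, %d rotatable groups\n",
              x$name, x$conformer_id, nrow(x$atoms),
              paste(sprintf("%s%d", names(counts), counts), collapse = " "),
              nrow(x$bonds), length(x$groups)))
  invisible(x)
}

#' Chemical formula of a template
#'
#' @param tpl A `mol_template`.
#' @return Named integer vector of element counts (Hill-ish order).
#' @export
template_formula <- function(tpl) {
  counts <- table(tpl$atoms$element)
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  out <- as.integer(counts[ord])
  names(out) <- ord
  out
}

#' Rotate a rotatable group
#'
#' Rotates the moved set of the selected group by `angle` degrees about the
#' axis bond.  Only moved-set atoms change; all bond lengths are preserved.
#'
#' @param tpl A `mol_template` (rotation applied to its own coordinates),
#'   or a template plus an explicit coordinate matrix via `xyz`.
#' @param group_index Index into `tpl$groups`.
#' @param angle Rotation angle in degrees.
#' @param xyz Optional coordinate matrix (rows ordered as `tpl$atoms`); if
#'   supplied the rotated matrix is returned instead of a template.
#' @return Updated template, or updated coordinate matrix if `xyz` given.
#' @export
rotate_group <- function(tpl, group_index, angle, xyz = NULL) {
  if (group_index < 1 || group_index > length(tpl$groups))
    stop("invalid group index ", group_index)
  g <- tpl$groups[[group_index]]
  ret_xyz <- !is.null(xyz)
  if (is.null(xyz)) xyz <- template_xyz(tpl)
  idx <- match(c(g$axis, g$moved), tpl$atoms$label)
  a <- xyz[idx[1], ]; b <- xyz[idx[2], ]
  mv <- idx[-(1:2)]
  xyz[mv, ] <- rotate_about_axis(xyz[mv, , drop = FALSE], a, b - a, angle)
  if (ret_xyz) return(xyz)
  tpl$atoms[, c("x", "y", "z")] <- xyz
  tpl
}

#' Write a template definition file
#'
#' Plain-text template format: `name`/`conformer` headers, an `[atoms]`
#' section (label element type_key x y z), `[bonds]`, and `[groups]`
#' (axis pair, `|`, moved labels).
#'
#' @param tpl A `mol_template`.
#' @param path Output file path.
#' @export
write_template <- function(tpl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("name", tpl$name), paste("conformer", tpl$conformer_id),
               "[atoms]"), con)
  writeLines(sprintf("%s %s %s %.9f %.9f %.9f", tpl$atoms$label,
                     tpl$atoms$element, tpl$atoms$type_key,
                     tpl$atoms$x, tpl$atoms$y, tpl$atoms$z), con)
  writeLines("[bonds]", con)
  writeLines(paste(tpl$bonds[, 1], tpl$bonds[, 2]), con)
  writeLines("[groups]", con)
  for (g in tpl$groups)
    writeLines(paste(g$axis[1], g$axis[2], "|", paste(g$moved, collapse = " ")), con)
  invisible(path)
}

#' Read a template definition file
#'
#' @param path Path to a template file written by [write_template()] (or
#'   hand-edited in the same format).
#' @return A validated `mol_template`.
#' @export
read_template <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  name <- sub("^name\\s+", "", grep("^name\\s", lines, value = TRUE)[1])
  conf <- sub("^conformer\\s+", "", grep("^conformer\\s", lines, value = TRUE)[1])
  sec <- cumsum(lines %in% c("[atoms]", "[bonds]", "[groups]"))
  body <- !(lines %in% c("[atoms]", "[bonds]", "[groups]")) & sec > 0
  cur <- character(length(lines))
  cur[lines == "[atoms]"] <- "atoms"; cur[lines == "[bonds]"] <- "bonds"
  cur[lines == "[groups]"] <- "groups"
  cur <- vapply(seq_along(lines), function(i) {
    tags <- cur[1:i][nzchar(cur[1:i])]
    if (length(tags)) tags[length(tags)] else ""
  }, "")
  parse_rows <- function(sel) strsplit(lines[body & cur == sel], "\\s+")
  arow <- parse_rows("atoms")
  atoms <- data.frame(
    label = vapply(arow, `[`, "", 1), element = vapply(arow, `[`, "", 2),
    type_key = vapply(arow, `[`, "", 3),
    x = as.numeric(vapply(arow, `[`, "", 4)),
    y = as.numeric(vapply(arow, `[`, "", 5)),
    z = as.numeric(vapply(arow, `[`, "", 6)), stringsAsFactors = FALSE)
  brow <- parse_rows("bonds")
  bonds <- do.call(rbind, lapply(brow, function(r) r[1:2]))
  groups <- lapply(parse_rows("groups"), function(r) {
    bar <- which(r == "|")
    list(axis = r[1:2], moved = r[(bar + 1):length(r)])
  })
  mol_template(name, conf, atoms, bonds, groups)
}

#' Load a molecular template
#'
#' Front door for template input: either a template definition file (see
#' [write_template()]) or a parsed crystal structure from [parse_cif()]
#' together with a `type_map` from atom label to force-field type key.
#' Hydrogens missing from a crystal source are added at standard riding
#' geometry (N-H 1.01 Angstrom, C-H 1.09 Angstrom).
#'
#' @param source File path of a template definition, or a `crystal_structure`.
#' @param type_map Named character vector label -> type_key (crystal source).
#' @param name,conformer_id Metadata for crystal-derived templates.
#' @return A validated `mol_template`.
#' @export
load_template <- function(source, type_map = NULL, name = "MOL",
                          conformer_id = "x") {
  if (is.character(source)) return(read_template(source))
  if (!inherits(source, "crystal_structure"))
    stop("source must be a template file path or a crystal_structure")
  template_from_crystal(source, type_map, name, conformer_id)
}
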