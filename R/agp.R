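# AGP v2.1 reading and writing (object rows W for scaffold components,
# U rows for 100-bp "scaffold" gaps with evidence "map", as produced by
# map-guided anchoring tools).

AGP_COLS <- c("object", "object_beg", "object_end", "part_number",
              "component_type", "component_id", "component_beg",
              "component_end", "orientation")

agp_from_layout <- function(layout, gap_size = 100) {
  rows <- list()
  for (ch in unique(layout$chrom)) {
    sub <- layout[layout$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    obj_pos <- 0L; part <- 0L
    for (i in seq_len(nrow(sub))) {
      if (i > 1) {
        part <- part + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          object = ch, object_beg = obj_pos + 1L,
          object_end = obj_pos + gap_size, part_number = part,
          component_type = "U", component_id = as.character(gap_size),
          component_beg = "scaffold", component_end = "yes",
          orientation = "map", stringsAsFactors = FALSE)
        obj_pos <- obj_pos + gap_size
      }
      part <- part + 1L
      len <- sub$length[i]
      rows[[length(rows) + 1L]] <- data.frame(
        object = ch, object_beg = obj_pos + 1L, object_end = obj_pos + len,
        part_number = part, component_type = "W",
        component_id = sub$scaffold[i], component_beg = "1",
        component_end = as.character(len),
        orientation = sub$orientation[i], stringsAsFactors = FALSE)
      obj_pos <- obj_pos + len
    }
  }
  structure(do.call(rbind, rows), names = AGP_COLS)
}

agp_from_anchors <- function(anchors, gap_size = 100) {
  layout_like <- data.frame(
    scaffold = anchors$part_id, chrom = anchors$group,
    start = anchors$order_cM, length = anchors$length,
    orientation = ifelse(anchors$orientation == "-", "-", "+"))
  agp <- agp_from_layout(layout_like, gap_size = gap_size)
  flagged <- anchors$part_id[anchors$orientation == "?"]
  attr(agp, "orientation_unknown") <- flagged
  agp
}

#' Read / write AGP v2.1
#'
#' The nine-column AGP format describing how scaffold components build
#' chromosome objects, with `W` component rows and `U` gap rows.
#' `read_agp()` and `write_agp()` round-trip losslessly.
#'
#' @param path AGP file.
#' @param agp an AGP data frame (as produced by [anchor_scaffolds()] or
#'   [fragment_genome()]).
#' @param comment header comment lines to write (without the leading #).
#' @return `read_agp()` returns the AGP data frame; `write_agp()` the
#'   path, invisibly.
#' @export
read_agp <- function(path) {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "integer", "character", "character",
                                   "character", "character", "character"))
  names(tab) <- AGP_COLS
  validate_agp(tab)
  tab
}

#' @rdname read_agp
#' @export
write_agp <- function(agp, path, comment = "AGP version 2.1") {
  validate_agp(agp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("##", comment), con)
  write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

validate_agp <- function(agp) {
  stopifnot(identical(names(agp), AGP_COLS))
  for (obj in unique(agp$object)) {
    sub <- agp[agp$object == obj, ]
    if (is.unsorted(sub$part_number, strictly = TRUE))
      stop_input("AGP parts out of order for ", obj)
    if (any(sub$object_beg[-1] != sub$object_end[-nrow(sub)] + 1L))
      stop_input("AGP components overlap or leave gaps in ", obj)
    ct <- sub$component_type
    if (any(ct[-1] == "U" & ct[-length(ct)] == "U"))
      stop_input("adjacent AGP gap rows in ", obj)
  }
  invisible(TRUE)
}
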