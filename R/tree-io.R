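#' Read and write vascular trees as JSON
#'
#' The canonical exchange format is a JSON object
#' `{"centerlines":[{"nodes":[[x,y,z,r],...],"parent":idx|null,"s_attach":f}],"units":"mm"}`
#' where `parent` is a 1-based centerline index (or `null` for the root) and
#' each node row holds position (mm) and radius (mm).  Round trips are
#' lossless to full double precision.
#'
#' @param tree A [vessel_tree()].
#' @param path File path.
#' @return `write_tree` invisibly returns `path`; `read_tree` returns a
#'   [vessel_tree()].
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "vessel_tree"))
  cls <- lapply(seq_along(tree$centerlines), function(i) {
    cl <- tree$centerlines[[i]]
    list(nodes = unname(cbind(cl$nodes, cl$radii)),
         parent = if (is.na(tree$parent[i])) NULL else tree$parent[i],
         s_attach = tree$s_attach[i])
  })
  jsonlite::write_json(list(centerlines = cls, units = "mm"), path,
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("tree JSON parse failure: ", conditionMessage(e))
                  })
  if (is.null(obj$centerlines)) {
    stop("tree JSON schema violation: missing field 'centerlines'")
  }
  cls <- obj$centerlines
  if (!length(cls)) {
    stop("tree JSON schema violation: field 'centerlines' is empty")
  }
  parsed <- lapply(seq_along(cls), function(i) {
    el <- cls[[i]]
    if (is.null(el$nodes) || !length(el$nodes)) {
      stop(sprintf("tree JSON schema violation: centerline %d missing field 'nodes'", i))
    }
    rows <- lapply(el$nodes, function(nd) {
      nd <- as.numeric(unlist(nd))
      if (length(nd) != 4) {
        stop(sprintf("tree JSON schema violation: centerline %d field 'nodes' rows must be [x, y, z, r]", i))
      }
      nd
    })
    nodes <- do.call(rbind, rows)
    p <- el$parent
    p <- if (is.null(p)) NA_integer_ else as.integer(p)
    sa <- el$s_attach
    sa <- if (is.null(sa)) 1 else as.numeric(sa)
    list(cl = centerline(nodes[, 1:3, drop = FALSE], nodes[, 4]),
         parent = p, s_attach = sa)
  })
  vessel_tree(lapply(parsed, `[[`, "cl"),
              parent = vapply(parsed, `[[`, 1L, "parent"),
              s_attach = vapply(parsed, `[[`, 1, "s_attach"))
}
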