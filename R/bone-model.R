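# Labeled bone models: a triangle mesh plus named articular-region face sets.
# Region names follow the consensus subdivision of the articular surfaces
# (condyles/trochlea split at the sulcus terminalis; plafond/medial malleolus
# split at the medial gutter).

FEMUR_REGIONS <- c("FEMORAL_HEAD", "FEMORAL_NECK", "MEDIAL_FEMORAL_CONDYLE",
                   "LATERAL_FEMORAL_CONDYLE", "TROCHLEA")
TIBFIB_REGIONS <- c("MEDIAL_TIBIAL_PLATEAU", "LATERAL_TIBIAL_PLATEAU",
                    "TIBIAL_PLAFOND", "MEDIAL_MALLEOLUS_FACET",
                    "LATERAL_MALLEOLUS_FACET")

#' Region labels recognized per bone
#'
#' @param bone `"FEMUR"` or `"TIBIA_FIBULA"`.
#' @return character vector of region names; all of them are required for a
#'   full alignment analysis.
#' @export
required_regions <- function(bone) {
  switch(match.arg(bone, c("FEMUR", "TIBIA_FIBULA")),
         FEMUR = FEMUR_REGIONS, TIBIA_FIBULA = TIBFIB_REGIONS)
}

#' Construct and validate a labeled bone model
#'
#' @param bone `"FEMUR"` or `"TIBIA_FIBULA"`.
#' @param side `"LEFT"` or `"RIGHT"`.
#' @param mesh a [leg_mesh()].
#' @param regions named list mapping region name to integer vector of 1-based
#'   face indices.
#' @param require_regions error if any region required for analysis is absent.
#' @return object of class `bone_model`.
#' @export
bone_model <- function(bone, side, mesh, regions, require_regions = TRUE) {
  bone <- match.arg(toupper(bone), c("FEMUR", "TIBIA_FIBULA"))
  side <- match.arg(toupper(side), c("LEFT", "RIGHT"))
  validate_mesh(mesh)
  allowed <- required_regions(bone)
  other <- setdiff(unlist(list(FEMUR_REGIONS, TIBFIB_REGIONS)), allowed)
  for (nm in names(regions)) {
    if (nm %in% other) {
      stop_legalign(sprintf("region %s does not belong on a %s model", nm, bone),
                    "legalign_label_error")
    }
    if (!nm %in% allowed) {
      stop_legalign(sprintf("unknown region name: %s", nm), "legalign_label_error")
    }
  }
  if (require_regions) {
    missing <- setdiff(allowed, names(regions))
    if (length(missing)) {
      stop_legalign(sprintf("required region %s missing", missing[1]),
                    "legalign_label_error")
    }
  }
  nf <- nrow(mesh$faces)
  regions <- lapply(regions, function(ix) sort(unique(as.integer(ix))))
  for (nm in names(regions)) {
    ix <- regions[[nm]]
    if (length(ix) == 0) {
      stop_legalign(sprintf("region %s is empty", nm), "legalign_label_error")
    }
    if (min(ix) < 1 || max(ix) > nf) {
      bad <- ix[ix < 1 | ix > nf][1]
      stop_legalign(sprintf("region %s references face %d outside [1, %d]",
                            nm, bad, nf), "legalign_validation_error")
    }
  }
  all_ix <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_ix)) {
    dup <- all_ix[duplicated(all_ix)][1]
    owners <- names(regions)[vapply(regions, function(ix) dup %in% ix, logical(1))]
    stop_legalign(sprintf("regions overlap (face %d in %s)", dup,
                          paste(owners, collapse = " and ")),
                  "legalign_validation_error")
  }
  structure(list(bone = bone, side = side, mesh = mesh, regions = regions),
            class = "bone_model")
}

#' @export
print.bone_model <- function(x, ...) {
  cat(sprintf("<bone_model> %s (%s): %d vertices, %d faces\n", x$bone, x$side,
              nrow(x$mesh$vertices), nrow(x$mesh$faces)))
  for (nm in names(x$regions)) {
    cat(sprintf("  %-24s %5d faces\n", nm, length(x$regions[[nm]])))
  }
  invisible(x)
}

# --- label file I/O ---------------------------------------------------------

LABEL_SCHEMA <- "legalign-labels-1"

#' Read / write the JSON region-label sidecar
#'
#' Schema: `{"schema": "legalign-labels-1", "regions": {"FEMORAL_HEAD":
#' [0-based face indices], ...}}`.
#'
#' @param path label JSON file.
#' @return named list of 1-based integer face-index vectors.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    stop_legalign(sprintf("label file not found: %s", path), "legalign_io_error")
  }
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_legalign(sprintf("cannot parse label JSON %s: %s",
                                          path, conditionMessage(e)),
                                  "legalign_format_error")
                  })
  if (!identical(doc$schema, LABEL_SCHEMA)) {
    stop_legalign(sprintf("label file %s has schema '%s', expected '%s'",
                          path, doc$schema %||% "<none>", LABEL_SCHEMA),
                  "legalign_format_error")
  }
  lapply(doc$regions, function(ix) as.integer(ix) + 1L)
}

#' @rdname read_labels
#' @param regions named list of 1-based face indices.
#' @export
write_labels <- function(regions, path) {
  doc <- list(schema = LABEL_SCHEMA,
              regions = lapply(regions, function(ix) as.integer(ix) - 1L))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a labeled bone model from disk
#'
#' The mesh may be STL or PLY. Labels come either from the JSON sidecar
#' (`label_path`) or, for PLY meshes carrying an integer `region_id` face
#' property, from that property plus a `region_map` in the sidecar
#' (`{"schema": "legalign-labels-1", "region_ids": {"FEMORAL_HEAD": 1, ...}}`).
#' Faces with ids not present in the map stay unlabeled.
#'
#' @param mesh_path STL or PLY file.
#' @param label_path JSON sidecar (region face lists or region-id map).
#' @param bone `"FEMUR"` or `"TIBIA_FIBULA"`.
#' @param side `"LEFT"` or `"RIGHT"`.
#' @param merge_eps vertex merge tolerance in mm.
#' @param require_regions error when analysis-required regions are absent.
#' @return a [bone_model()].
#' @export
read_bone_model <- function(mesh_path, label_path, bone, side,
                            merge_eps = 1e-6, require_regions = TRUE) {
  mesh <- read_mesh(mesh_path, merge_eps = merge_eps)
  doc <- tryCatch(jsonlite::read_json(label_path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_legalign(sprintf("cannot parse label JSON %s: %s",
                                          label_path, conditionMessage(e)),
                                  "legalign_format_error")
                  })
  if (!identical(doc$schema, LABEL_SCHEMA)) {
    stop_legalign(sprintf("label file %s has schema '%s', expected '%s'",
                          label_path, doc$schema %||% "<none>", LABEL_SCHEMA),
                  "legalign_format_error")
  }
  props <- attr(mesh, "face_props")
  if (!is.null(doc$region_ids)) {
    if (is.null(props) || is.null(props$region_id)) {
      stop_legalign("label file maps region ids but mesh has no region_id face property",
                    "legalign_label_error")
    }
    regions <- lapply(doc$region_ids, function(id) which(props$region_id == id))
    regions <- regions[lengths(regions) > 0]
  } else if (!is.null(doc$regions)) {
    regions <- lapply(doc$regions, function(ix) as.integer(ix) + 1L)
  } else {
    stop_legalign(sprintf("label file %s has neither 'regions' nor 'region_ids'",
                          label_path), "legalign_format_error")
  }
  bone_model(bone, side, mesh, regions, require_regions = require_regions)
}

#' Write a labeled bone model (mesh + JSON sidecar)
#'
#' @param model a [bone_model()].
#' @param mesh_path output STL (binary) or PLY path.
#' @param label_path output JSON sidecar path.
#' @return invisibly, the mesh path.
#' @export
write_bone_model <- function(model, mesh_path, label_path) {
  ext <- tolower(tools::file_ext(mesh_path))
  if (ext == "ply") write_ply(model$mesh, mesh_path) else write_stl(model$mesh, mesh_path)
  write_labels(model$regions, label_path)
  invisible(mesh_path)
}

# Apply a rigid transform to the whole model (labels are face-indexed, so
# they are untouched).
transform_bone_model <- function(model, tf) {
  model$mesh <- transform_mesh(model$mesh, tf)
  model
}

# Mirror a model through the plane x = 0 (patient left/right). Face winding
# is flipped to keep outward normals outward; the side flag flips.
mirror_bone_model <- function(model) {
  v <- model$mesh$vertices
  v[, 1] <- -v[, 1]
  f <- model$mesh$faces[, c(1, 3, 2), drop = FALSE]
  model$mesh <- leg_mesh(v, f, validate = FALSE)
  model$side <- if (model$side == "RIGHT") "LEFT" else "RIGHT"
  model
}

# --- surface sampling -------------------------------------------------------

#' Materialize a labeled region as a weighted point set
#'
#' `FACE_CENTROIDS` (the default everywhere downstream) returns per-face
#' centroids weighted by triangle area, making fits tessellation-invariant;
#' `VERTICES` returns the unique region vertices with unit weight.
#'
#' @param model a [bone_model()].
#' @param region region name.
#' @param mode `"FACE_CENTROIDS"` or `"VERTICES"`.
#' @return list with `points` (n x 3 matrix) and `weights` (length n).
#' @export
region_points <- function(model, region, mode = c("FACE_CENTROIDS", "VERTICES")) {
  mode <- match.arg(mode)
  ix <- model$regions[[region]]
  if (is.null(ix) || length(ix) == 0) {
    stop_legalign(sprintf("region %s missing or empty", region),
                  "legalign_label_error")
  }
  sub <- leg_mesh(model$mesh$vertices, model$mesh$faces[ix, , drop = FALSE],
                  validate = FALSE)
  if (mode == "FACE_CENTROIDS") {
    list(points = face_centroids(sub), weights = face_areas(sub))
  } else {
    vix <- sort(unique(as.integer(sub$faces)))
    list(points = model$mesh$vertices[vix, , drop = FALSE],
         weights = rep(1, length(vix)))
  }
}

# Unique vertex indices of a region (for extremal-point searches).
region_vertex_indices <- function(model, region) {
  ix <- model$regions[[region]]
  if (is.null(ix) || length(ix) == 0) {
    stop_legalign(sprintf("region %s missing or empty", region),
                  "legalign_label_error")
  }
  sort(unique(as.integer(model$mesh$faces[ix, ])))
}

#' Area-weighted centroid of a labeled articular surface
#'
#' @param model a [bone_model()].
#' @param region region name.
#' @return numeric length-3 centroid (mm).
#' @export
surface_centroid <- function(model, region) {
  rp <- region_points(model, region, "FACE_CENTROIDS")
  w <- rp$weights
  if (sum(w) <= 1e-12) {
    stop_legalign(sprintf("region %s has zero total area", region),
                  "legalign_degeneracy_error")
  }
  as.numeric(colSums(rp$points * w) / sum(w))
}

#' Per-region surface areas
#'
#' @param model a [bone_model()].
#' @return tibble with columns `region` and `area_mm2`.
#' @export
region_areas <- function(model) {
  tibble::tibble(
    region = names(model$regions),
    area_mm2 = vapply(names(model$regions), function(nm) {
      sum(face_areas(leg_mesh(model$mesh$vertices,
                              model$mesh$faces[model$regions[[nm]], , drop = FALSE],
                              validate = FALSE)))
    }, numeric(1))
  )
}
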