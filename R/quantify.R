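#' Volume, coverage and object count
#'
#' `V_N` = foreground voxels times voxel volume (um^3); `VC_N` = percentage
#' of the image volume covered (0-100); `N_N` = number of 26-connected
#' objects.
#'
#' @param mask a [binary_mask].
#' @return list with `volume_um3`, `coverage_pct`, `n_objects`.
#' @export
compute_volume_coverage <- function(mask) {
  vs <- mask$voxel_size
  fg <- sum(mask$voxels)
  lab <- cpp_label26(as.vector(mask$voxels > 0), dim(mask$voxels))
  list(volume_um3 = fg * prod(vs),
       coverage_pct = 100 * fg / length(mask$voxels),
       n_objects = attr(lab, "n_components"))
}

#' Surface voxels and surface-to-volume ratio
#'
#' A surface voxel is a foreground voxel with at least one of its 6 face
#' neighbours background (or lying on the image border). `S_N` is reported in
#' um^3 (surface-voxel count times voxel volume) for comparability between
#' experiments -- dimensionally a volume, kept as the convention prints it --
#' with a conventional um^2 area (count times the mean face area) emitted
#' alongside. `SV_ratio` = surface count / foreground count, in `[0, 1]`.
#'
#' @param mask a [binary_mask].
#' @return list with `surface_um3`, `sv_ratio`, `surface_voxels`,
#'   `surface_um2`, and `surface` (logical array).
#' @export
compute_surface <- function(mask) {
  v <- mask$voxels > 0
  d <- dim(v)
  shift_bg <- function(ax, dir) {
    ## TRUE where the face neighbour along axis ax/direction dir is bg/border
    out <- array(TRUE, dim = d)
    n <- d[ax]
    if (n == 1L) return(out)
    src <- switch(ax, `1` = 2, `2` = 2, `3` = 2)
    if (ax == 1L) {
      if (dir > 0) out[1:(n - 1), , ] <- !v[2:n, , ]
      else out[2:n, , ] <- !v[1:(n - 1), , ]
    } else if (ax == 2L) {
      if (dir > 0) out[, 1:(n - 1), ] <- !v[, 2:n, ]
      else out[, 2:n, ] <- !v[, 1:(n - 1), ]
    } else {
      if (dir > 0) out[, , 1:(n - 1)] <- !v[, , 2:n]
      else out[, , 2:n] <- !v[, , 1:(n - 1)]
    }
    out
  }
  surf <- v & (shift_bg(1L, 1) | shift_bg(1L, -1) |
               shift_bg(2L, 1) | shift_bg(2L, -1) |
               shift_bg(3L, 1) | shift_bg(3L, -1))
  ns <- sum(surf); nf <- sum(v)
  vs <- mask$voxel_size
  face_area <- mean(c(vs[["dx"]] * vs[["dy"]], vs[["dx"]] * vs[["dz"]],
                      vs[["dy"]] * vs[["dz"]]))
  list(surface_um3 = ns * prod(vs),
       sv_ratio = if (nf > 0) ns / nf else 0,
       surface_voxels = ns,
       surface_um2 = ns * face_area,
       surface = surf)
}

#' Euclidean distance map and centerline thickness
#'
#' Anisotropy-aware 3D Euclidean distance transform of the foreground
#' (distance in um from each foreground voxel to the nearest background
#' voxel, physical metric, not voxel-index metric). The thickness statistic
#' `T_N` is the mean EDM value sampled over the skeleton voxels -- the
#' distance from the local centerline to the surface, i.e. a local radius
#' (no factor 2 for diameter is applied). The maximum is reported as well.
#'
#' @param mask a [binary_mask].
#' @param skeleton optional [skeletonize_3d] result (computed if missing).
#' @return list with `edm` (3D array, um), `thickness_um` (T_N),
#'   `thickness_max_um`.
#' @export
compute_edm_thickness <- function(mask, skeleton = NULL) {
  vs <- mask$voxel_size
  edm <- array(cpp_edt(as.vector(mask$voxels > 0), dim(mask$voxels),
                       c(vs[["dz"]], vs[["dy"]], vs[["dx"]])),
               dim = dim(mask$voxels))
  if (is.null(skeleton)) skeleton <- skeletonize_3d(mask)
  sk <- skeleton$voxels > 0
  if (!any(sk)) {
    warning("empty skeleton: thickness reported as 0")
    return(list(edm = edm, thickness_um = 0, thickness_max_um = 0))
  }
  list(edm = edm, thickness_um = mean(edm[sk]),
       thickness_max_um = max(edm[sk]))
}

## ---- skeleton graph --------------------------------------------------------

## adjacency of skeleton voxels by linear index; returns list of integer
## vectors (indices into the voxel list, not linear indices)
skeleton_adjacency <- function(lin, d) {
  nz <- d[1]; ny <- d[2]
  z <- (lin - 1) %% nz
  y <- ((lin - 1) %/% nz) %% ny
  x <- (lin - 1) %/% (nz * ny)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  adj <- vector("list", length(lin))
  for (k in seq_len(nrow(offs))) {
    zz <- z + offs$dz[k]; yy <- y + offs$dy[k]; xx <- x + offs$dx[k]
    ok <- zz >= 0 & zz < nz & yy >= 0 & yy < ny & xx >= 0 & xx < d[3]
    nb_lin <- zz + nz * (yy + ny * xx) + 1
    hit <- match(ifelse(ok, nb_lin, NA_integer_), lin)
    sel <- which(!is.na(hit))
    for (i in sel) adj[[i]] <- c(adj[[i]], hit[i])
  }
  adj
}

step_length_um <- function(lin_a, lin_b, d, vs) {
  nz <- d[1]; ny <- d[2]
  za <- (lin_a - 1) %% nz; zb <- (lin_b - 1) %% nz
  ya <- ((lin_a - 1) %/% nz) %% ny; yb <- ((lin_b - 1) %/% nz) %% ny
  xa <- (lin_a - 1) %/% (nz * ny); xb <- (lin_b - 1) %/% (nz * ny)
  sqrt(((za - zb) * vs[["dz"]])^2 + ((ya - yb) * vs[["dy"]])^2 +
         ((xa - xb) * vs[["dx"]])^2)
}

#' 3D thinning skeletonization
#'
#' Homotopy-preserving layer-by-layer thinning of the mask to a 1-voxel-wide
#' centerline: directional (6-subiteration) removal of simple points
#' (26-connectivity for foreground, 6 for background) with endpoint
#' preservation, followed by graph construction with 26-connectivity. A
#' junction is a maximal 26-connected cluster of skeleton voxels having more
#' than 2 skeleton neighbours, counted once. Optional pruning removes
#' terminal branches shorter than `prune_below_um` (off by default).
#'
#' @param mask a [binary_mask].
#' @param prune_below_um prune terminal branches shorter than this (um).
#' @return A `skeleton3d`: list with `voxels` (0/1 array), `voxel_size`,
#'   `graph` (`nodes` data.frame and `branches` list), `n_trees`.
#' @export
skeletonize_3d <- function(mask, prune_below_um = 0) {
  d <- dim(mask$voxels)
  thin <- cpp_thin3d(as.vector(mask$voxels > 0), d)
  sk <- array(as.integer(thin), dim = d)
  out <- build_skeleton(sk, mask$voxel_size)
  if (prune_below_um > 0 && length(out$graph$branches)) {
    drop <- vapply(out$graph$branches, function(b) {
      b$terminal && b$length_um < prune_below_um
    }, TRUE)
    if (any(drop)) {
      for (b in out$graph$branches[drop]) sk[b$path] <- 0L
      out <- build_skeleton(sk, mask$voxel_size)
    }
  }
  out
}

## assemble the skeleton graph from a thinned 0/1 array
build_skeleton <- function(sk, voxel_size) {
  d <- dim(sk)
  lin <- which(sk > 0)
  empty <- list(voxels = sk, voxel_size = voxel_size,
                graph = list(nodes = data.frame(), branches = list()),
                n_trees = 0L)
  class(empty) <- "skeleton3d"
  if (!length(lin)) return(empty)

  lab_all <- cpp_label26(as.vector(sk > 0), d)
  n_trees <- attr(lab_all, "n_components")
  deg_arr <- cpp_neighbour_count26(as.vector(sk > 0), d)
  deg <- deg_arr[lin]
  adj <- skeleton_adjacency(lin, d)
  is_junc <- deg > 2L

  ## junction clusters
  jmask <- array(FALSE, dim = d)
  jmask[lin[is_junc]] <- TRUE
  jlab_arr <- cpp_label26(as.vector(jmask), d)
  n_junctions <- attr(jlab_arr, "n_components")
  jcluster <- ifelse(is_junc, jlab_arr[lin], 0L)

  vs <- voxel_size
  branches <- list()
  visited <- logical(length(lin))

  trace_from <- function(i0, from_cluster) {
    ## walk along degree<=2 voxels starting at regular voxel i0
    path <- i0
    visited[i0] <<- TRUE
    prev <- 0L
    cur <- i0
    end_cluster <- 0L
    repeat {
      nxt <- adj[[cur]]
      nxt <- nxt[nxt != prev]
      jn <- nxt[jcluster[nxt] > 0L]
      if (from_cluster > 0L && length(path) == 1L) {
        jn <- jn[jcluster[jn] != from_cluster]
      }
      if (length(jn)) { end_cluster <- jcluster[jn[1]]; break }
      nxt <- nxt[!visited[nxt] & jcluster[nxt] == 0L]
      if (!length(nxt)) break
      prev <- cur
      cur <- nxt[1]
      visited[cur] <<- TRUE
      path <- c(path, cur)
    }
    list(path = path, end_cluster = end_cluster)
  }

  finish_branch <- function(path_idx, start_cluster, end_cluster) {
    plin <- lin[path_idx]
    len <- 0
    if (length(plin) > 1) {
      len <- sum(step_length_um(plin[-length(plin)], plin[-1], d, vs))
    }
    ## include the steps into the junction clusters at either end
    attach_len <- function(end_idx, cl) {
      if (cl == 0L) return(0)
      cand <- adj[[end_idx]]
      cand <- cand[jcluster[cand] == cl]
      if (!length(cand)) return(0)
      min(step_length_um(rep(lin[end_idx], length(cand)), lin[cand], d, vs))
    }
    len <- len + attach_len(path_idx[1], start_cluster) +
      attach_len(path_idx[length(path_idx)], end_cluster)
    n_end_eps <- sum(deg[c(path_idx[1], path_idx[length(path_idx)])] <= 1L &
                       c(start_cluster, end_cluster) == 0L)
    list(path = lin[path_idx], length_um = len,
         clusters = c(start_cluster, end_cluster),
         terminal = (start_cluster == 0L) || (end_cluster == 0L),
         closed = FALSE, n_endpoints = n_end_eps)
  }

  regular <- which(!is_junc)
  ## 1) branches rooted at junction clusters
  for (i in regular) {
    if (visited[i]) next
    touching <- unique(jcluster[adj[[i]]][jcluster[adj[[i]]] > 0L])
    if (!length(touching)) next
    tr <- trace_from(i, touching[1])
    branches[[length(branches) + 1L]] <-
      finish_branch(tr$path, touching[1], tr$end_cluster)
  }
  ## 2) junction-free paths (start from unvisited endpoints)
  for (i in regular) {
    if (visited[i] || deg[i] > 1L) next
    tr <- trace_from(i, 0L)
    branches[[length(branches) + 1L]] <-
      finish_branch(tr$path, 0L, tr$end_cluster)
  }
  ## 3) pure cycles: remaining unvisited degree-2 voxels
  for (i in regular) {
    if (visited[i]) next
    tr <- trace_from(i, 0L)
    br <- finish_branch(tr$path, 0L, tr$end_cluster)
    if (length(br$path) > 1L) {
      ## close the loop if the two ends are adjacent
      ends_adj <- tr$path[length(tr$path)] %in% adj[[tr$path[1]]]
      if (ends_adj) {
        br$length_um <- br$length_um +
          step_length_um(br$path[1], br$path[length(br$path)], d, vs)
        br$closed <- TRUE
        br$n_endpoints <- 0L
      }
    }
    branches[[length(branches) + 1L]] <- br
  }
  ## 4) direct cluster-cluster contacts (no regular voxel in between)
  if (n_junctions > 1L) {
    seen_pairs <- character(0)
    for (i in which(is_junc)) {
      for (j in adj[[i]]) {
        ci <- jcluster[i]; cj <- jcluster[j]
        if (cj > 0L && cj != ci) {
          key <- paste(sort(c(ci, cj)), collapse = "-")
          if (!(key %in% seen_pairs)) {
            seen_pairs <- c(seen_pairs, key)
            branches[[length(branches) + 1L]] <-
              list(path = integer(0),
                   length_um = step_length_um(lin[i], lin[j], d, vs),
                   clusters = c(ci, cj), terminal = FALSE, closed = FALSE,
                   n_endpoints = 0L)
          }
        }
      }
    }
  }

  n_endpoints <- sum(deg == 1L) + sum(deg == 0L)
  ## branches incident per cluster -> triple/quadruple points
  inc <- integer(n_junctions)
  for (b in branches) {
    for (cl in b$clusters) if (cl > 0L) inc[cl] <- inc[cl] + 1L
  }
  nodes <- data.frame(
    cluster = seq_len(n_junctions),
    incident_branches = if (n_junctions) inc else integer(0))

  res <- list(voxels = sk, voxel_size = voxel_size,
              graph = list(nodes = nodes, branches = branches,
                           degree = deg, lin = lin),
              n_trees = n_trees,
              n_junctions = n_junctions,
              n_endpoints = n_endpoints)
  class(res) <- "skeleton3d"
  res
}

#' Skeleton statistics
#'
#' Branch lengths are calibrated anisotropic path lengths (each step
#' contributes `sqrt((dx Dx)^2 + (dy Dy)^2 + (dz Dz)^2)`). Junctions are
#' voxel clusters counted once; triple/quadruple points are junctions with
#' 3/4 incident branches. `L_N` is the total skeleton length in um and `BL`
#' the mean branch length.
#'
#' @param skeleton a `skeleton3d` from [skeletonize_3d].
#' @return list with `n_trees`, `n_branches`, `n_junctions`, `n_endpoints`,
#'   `n_triple_points`, `n_quadruple_points`, `max_branch_length_um`,
#'   `mean_branch_length_um`, `total_length_um`, `sum_voxels`.
#' @export
skeleton_statistics <- function(skeleton) {
  br <- skeleton$graph$branches
  lens <- vapply(br, function(b) b$length_um, 0)
  nodes <- skeleton$graph$nodes
  list(n_trees = skeleton$n_trees,
       n_branches = length(br),
       n_junctions = if (is.null(skeleton$n_junctions)) 0L else skeleton$n_junctions,
       n_endpoints = if (is.null(skeleton$n_endpoints)) 0L else skeleton$n_endpoints,
       n_triple_points = if (nrow(nodes)) sum(nodes$incident_branches == 3L) else 0L,
       n_quadruple_points = if (nrow(nodes)) sum(nodes$incident_branches == 4L) else 0L,
       max_branch_length_um = if (length(lens)) max(lens) else 0,
       mean_branch_length_um = if (length(lens)) mean(lens) else 0,
       total_length_um = sum(lens),
       sum_voxels = sum(skeleton$voxels))
}

#' Apicobasal texture of original, segmented and skeletonized data
#'
#' Applies [apicobasal_profile] to the three co-registered representations.
#'
#' @param original [vol_image]; `mask` [binary_mask]; `skeleton` a
#'   `skeleton3d`.
#' @return Named list of three `zonation_profile`s
#'   (`original`, `segmented`, `skeleton`).
#' @export
apicobasal_texture <- function(original, mask, skeleton) {
  if (!all(img_dim(original) == dim(mask$voxels)) ||
      !all(dim(mask$voxels) == dim(skeleton$voxels))) {
    stop("original, mask and skeleton must share one shape")
  }
  list(original = apicobasal_profile(original),
       segmented = apicobasal_profile(mask),
       skeleton = apicobasal_profile(
         binary_mask(skeleton$voxels, skeleton$voxel_size)))
}

#' Full morphometric quantification of one mask
#'
#' Runs volume/coverage, surface, EDM thickness, skeleton extraction and
#' statistics, heights and (when `original` is supplied) apicobasal texture,
#' returning the per-stack feature record. With `out_dir`, writes the
#' standard output tree: `QuantificationResults.csv` (headers exactly
#' `Volume [um3]`, `PercCov [%]`, `SurfaceVol [um3]`, `Thickness [um]`),
#' `SkeletonStats.csv`, and folders `outZone/`, `QuantEDM/`, `QuantSkel/`
#' with stacks plus `MAX_` MIPs.
#'
#' @param mask a [binary_mask] (error instructs to segment first otherwise).
#' @param original optional co-registered intensity [vol_image].
#' @param sigma_um sigma used during standardization (for the height
#'   bookkeeping).
#' @param prune_below_um skeleton pruning threshold (0 = off, the default).
#' @param out_dir optional output directory.
#' @param name record label.
#' @return A `feature_record` (named list; see [skeleton_statistics] for the
#'   skeleton block).
#' @export
quantify_stack <- function(mask, original = NULL, sigma_um = 0,
                           prune_below_um = 0, out_dir = NULL,
                           name = "stack") {
  if (!inherits(mask, "binary_mask")) {
    stop("quantify_stack expects a binary mask: segment the stack first")
  }
  vc <- compute_volume_coverage(mask)
  surf <- compute_surface(mask)
  skel <- skeletonize_3d(mask, prune_below_um = prune_below_um)
  edm <- compute_edm_thickness(mask, skel)
  st <- skeleton_statistics(skel)
  h <- measure_heights(mask, sigma_um = sigma_um)
  rec <- c(list(name = name,
                image_height_um = h$image_height_um,
                retina_height_um = h$retina_height_um,
                mg_height_um = h$mg_height_um,
                n_objects = vc$n_objects,
                volume_um3 = vc$volume_um3,
                coverage_pct = vc$coverage_pct,
                surface_um3 = surf$surface_um3,
                surface_um2 = surf$surface_um2,
                sv_ratio = surf$sv_ratio,
                thickness_um = edm$thickness_um,
                thickness_max_um = edm$thickness_max_um),
           st)
  class(rec) <- "feature_record"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_quant_outputs(list(rec), out_dir)
    vsz <- mask$voxel_size
    edm_img <- vol_image(edm$edm, vsz, "float", name = paste0("EDM_", name))
    write_stack(edm_img, file.path(out_dir, "QuantEDM",
                                   paste0(edm_img$name, ".tif")))
    write_stack(max_projection(edm_img),
                file.path(out_dir, "QuantEDM",
                          paste0("MAX_EDM_", name, ".tif")))
    sk_img <- vol_image(skel$voxels * 255L, vsz, "8",
                        name = paste0("Skel_", name))
    write_stack(sk_img, file.path(out_dir, "QuantSkel",
                                  paste0(sk_img$name, ".tif")))
    write_stack(max_projection(sk_img),
                file.path(out_dir, "QuantSkel",
                          paste0("MAX_Skel_", name, ".tif")))
    profs <- list(segmented = apicobasal_profile(mask))
    if (!is.null(original)) profs$original <- apicobasal_profile(original)
    profs$skeleton <- apicobasal_profile(binary_mask(skel$voxels, vsz))
    export_zonation(profs, file.path(out_dir, "outZone"))
  }
  rec
}

#' Write batch quantification CSVs
#'
#' @param records list of `feature_record`s.
#' @param out_dir output directory.
#' @return Paths of the two CSVs, invisibly.
#' @export
write_quant_outputs <- function(records, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qr <- data.frame(
    check.names = FALSE,
    `Image` = vapply(records, function(r) r$name, ""),
    `Volume [um3]` = vapply(records, function(r) r$volume_um3, 0),
    `PercCov [%]` = vapply(records, function(r) r$coverage_pct, 0),
    `SurfaceVol [um3]` = vapply(records, function(r) r$surface_um3, 0),
    `Thickness [um]` = vapply(records, function(r) r$thickness_um, 0))
  p1 <- file.path(out_dir, "QuantificationResults.csv")
  utils::write.csv(qr, p1, row.names = FALSE)
  ss <- data.frame(
    check.names = FALSE,
    `Image` = vapply(records, function(r) r$name, ""),
    `max branch length` = vapply(records, function(r) r$max_branch_length_um, 0),
    `mean branch length` = vapply(records, function(r) r$mean_branch_length_um, 0),
    `# of trees` = vapply(records, function(r) as.numeric(r$n_trees), 0),
    `# of branches` = vapply(records, function(r) as.numeric(r$n_branches), 0),
    `# of junctions` = vapply(records, function(r) as.numeric(r$n_junctions), 0),
    `# of endpoints` = vapply(records, function(r) as.numeric(r$n_endpoints), 0),
    `# of triple points` = vapply(records, function(r) as.numeric(r$n_triple_points), 0),
    `# of quadruple points` = vapply(records, function(r) as.numeric(r$n_quadruple_points), 0),
    `sum of voxels` = vapply(records, function(r) as.numeric(r$sum_voxels), 0))
  p2 <- file.path(out_dir, "SkeletonStats.csv")
  utils::write.csv(ss, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
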