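#' Provenance of the implemented radiomic features
#'
#' Lists every feature the extractor emits with its class, defining formula,
#' and the extraction parameters it depends on. Useful as a machine-readable
#' companion to exported feature tables and for auditing which variant of a
#' textbook formula is in use (e.g. population-moment skewness, direction
#' averaging for GLCM/GLRLM).
#'
#' @return data.frame with columns `feature`, `class`, `formula`,
#'   `parameters`.
#' @export
feature_provenance <- function() {
  row <- function(feature, class, formula, parameters = "") {
    data.frame(feature = feature, class = class, formula = formula,
               parameters = parameters, stringsAsFactors = FALSE)
  }
  rbind(
    row("shape_voxel_volume", "shape", "N_voxels * prod(voxel_size)"),
    row("shape_mesh_volume", "shape",
        "volume enclosed by the triangulated 0.5-isosurface",
        "box-averaged dual field, Kuhn tetrahedra"),
    row("shape_surface_area", "shape",
        "area of the triangulated 0.5-isosurface",
        "box-averaged dual field, Kuhn tetrahedra"),
    row("shape_sphericity", "shape", "(36 pi V^2)^(1/3) / A"),
    row("shape_elongation", "shape", "sqrt(lambda_2 / lambda_1)",
        "eigenvalues of the voxel-coordinate covariance"),
    row("shape_major_axis_length", "shape", "4 sqrt(lambda_1)"),
    row("shape_max_3d_diameter", "shape",
        "max pairwise distance between surface-voxel centres"),
    row("firstorder_mean", "firstorder", "mean(x)"),
    row("firstorder_median", "firstorder", "median(x)"),
    row("firstorder_minimum", "firstorder", "min(x)"),
    row("firstorder_maximum", "firstorder", "max(x)"),
    row("firstorder_range", "firstorder", "max(x) - min(x)"),
    row("firstorder_variance", "firstorder", "mean((x - mean(x))^2)",
        "population moment"),
    row("firstorder_skewness", "firstorder", "m3 / m2^(3/2)",
        "Fisher-Pearson, population moments"),
    row("firstorder_energy", "firstorder", "sum(x^2)"),
    row("firstorder_total_energy", "firstorder",
        "sum(x^2) * prod(voxel_size)"),
    row("firstorder_rms", "firstorder", "sqrt(mean(x^2))"),
    row("glcm_idm", "glcm", "sum p(i,j) / (1 + (i-j)^2)",
        "13 directions, distance 1, symmetric, averaged"),
    row("glcm_cluster_shade", "glcm",
        "sum (i + j - mu_x - mu_y)^3 p(i,j)",
        "13 directions, distance 1, symmetric, averaged"),
    row("glrlm_gln", "glrlm", "sum_i (sum_j P(i,j))^2 / N_r",
        "13 directions, averaged"),
    row("glrlm_rln", "glrlm", "sum_j (sum_i P(i,j))^2 / N_r",
        "13 directions, averaged"),
    row("glszm_sae", "glszm", "sum P(i,j) / j^2 / N_z", "26-connectivity"),
    row("glszm_szn", "glszm", "sum_j (sum_i P(i,j))^2 / N_z",
        "26-connectivity"),
    row("glszm_sznn", "glszm", "sum_j (sum_i P(i,j))^2 / N_z^2",
        "26-connectivity"),
    row("glszm_gln", "glszm", "sum_i (sum_j P(i,j))^2 / N_z",
        "26-connectivity"),
    row("glszm_lalgle", "glszm", "sum P(i,j) j^2 / i^2 / N_z",
        "26-connectivity"),
    row("gldm_dn", "gldm", "sum_j (sum_i P(i,j))^2 / N_d",
        "alpha = 0, 26-connectivity"),
    row("gldm_gln", "gldm", "sum_i (sum_j P(i,j))^2 / N_d",
        "alpha = 0, 26-connectivity"),
    row("ngtdm_coarseness", "ngtdm", "1 / sum p_i s_i",
        "26-connectivity, capped at 1e6"))
}
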