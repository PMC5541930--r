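#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labelling of a species-code raster under the
// four-neighbour rule. Background is code 0. Two adjacent cells belong to the
// same patch iff they share the species code; the perimeter of a patch counts
// every unit edge between one of its cells and anything outside the patch
// (background, another species, or the grid boundary).
// [[Rcpp::export]]
List label_patches_cpp(IntegerMatrix grid) {
  const int nr = grid.nrow(), nc = grid.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> species, area, perim;
  std::vector<int> stack;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  int next_id = 0;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (grid(i, j) <= 0 || lab(i, j) != 0) continue;
      ++next_id;
      const int code = grid(i, j);
      int a = 0, p = 0;
      lab(i, j) = next_id;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int ci = idx % nr, cj = idx / nr;
        ++a;
        for (int k = 0; k < 4; ++k) {
          const int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc || grid(ni, nj) != code) {
            ++p;  // face exposed to outside of this patch
            continue;
          }
          if (lab(ni, nj) == 0) {
            lab(ni, nj) = next_id;
            stack.push_back(ni + nj * nr);
          }
        }
      }
      species.push_back(code);
      area.push_back(a);
      perim.push_back(p);
    }
  }
  return List::create(_["labels"] = lab,
                      _["species_code"] = wrap(species),
                      _["area_cells"] = wrap(area),
                      _["perimeter_edges"] = wrap(perim));
}

// Eden-type stochastic blob growth: each patch starts from a uniformly random
// free cell and accretes uniformly random frontier cells until it reaches its
// target area or is boxed in. Overlaps are resolved first-come: growth never
// enters occupied cells. Uses R's RNG, so results are reproducible under
// set.seed(). Patches whose seed cell cannot be placed (grid saturated) are
// silently skipped; realised areas may fall short of targets when blocked.
// [[Rcpp::export]]
IntegerMatrix grow_blobs_cpp(int nr, int nc, IntegerVector species,
                             IntegerVector target_area, int max_seed_tries) {
  IntegerMatrix grid(nr, nc);
  const int n = species.size();
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  std::vector<int> frontier;
  RNGScope scope;

  for (int b = 0; b < n; ++b) {
    int si = -1, sj = -1;
    for (int t = 0; t < max_seed_tries; ++t) {
      int ii = (int)(unif_rand() * nr);
      int jj = (int)(unif_rand() * nc);
      if (ii >= nr) ii = nr - 1;
      if (jj >= nc) jj = nc - 1;
      if (grid(ii, jj) == 0) { si = ii; sj = jj; break; }
    }
    if (si < 0) continue;
    grid(si, sj) = species[b];
    int a = 1;
    frontier.clear();
    for (int k = 0; k < 4; ++k) {
      const int ni = si + di[k], nj = sj + dj[k];
      if (ni >= 0 && ni < nr && nj >= 0 && nj < nc && grid(ni, nj) == 0)
        frontier.push_back(ni + nj * nr);
    }
    while (a < target_area[b] && !frontier.empty()) {
      int k = (int)(unif_rand() * frontier.size());
      if (k >= (int)frontier.size()) k = frontier.size() - 1;
      const int idx = frontier[k];
      frontier[k] = frontier.back();
      frontier.pop_back();
      const int ci = idx % nr, cj = idx / nr;
      if (grid(ci, cj) != 0) continue;  // claimed since it was queued
      grid(ci, cj) = species[b];
      ++a;
      for (int q = 0; q < 4; ++q) {
        const int ni = ci + di[q], nj = cj + dj[q];
        if (ni >= 0 && ni < nr && nj >= 0 && nj < nc && grid(ni, nj) == 0)
          frontier.push_back(ni + nj * nr);
      }
    }
  }
  return grid;
}
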