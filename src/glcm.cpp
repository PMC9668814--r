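#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel-wise sliding-cube GLCM texture maps.
//
// For every voxel, a cube of edge `cube_size` centred on it (cropped at the
// volume boundary) defines a window; gray-level pairs (v, v+offset) with both
// members foreground (level >= 1) are accumulated over all offsets into one
// symmetrized co-occurrence histogram, normalized to probabilities, and the
// six scalar features are evaluated.  Centres whose window contributes no
// valid pair get 0 in every map.  Correctness is defined by the naive R
// oracle in the test suite; this is just the fast path.

static const double LOG2 = 0.6931471805599453;

// [[Rcpp::export(name = ".texture_maps_cpp")]]
List texture_maps_cpp(IntegerVector vol, IntegerVector dims, int n_levels,
                      IntegerMatrix offsets, int cube_size) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int G = n_levels;
  const int h = (cube_size - 1) / 2;
  const int n_off = offsets.nrow();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;

  NumericVector ent(nvox), sent(nvox), dent(nvox), ene(nvox), con(nvox), hom(nvox);
  std::vector<double> counts((size_t)G * G);
  std::vector<double> qsum(2 * G + 1), qdiff(G);
  std::vector<int> ox(n_off), oy(n_off), oz(n_off);
  for (int k = 0; k < n_off; ++k) {
    ox[k] = offsets(k, 0); oy[k] = offsets(k, 1); oz[k] = offsets(k, 2);
  }

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int x0 = std::max(0, x - h), x1 = std::min(nx - 1, x + h);
        const int y0 = std::max(0, y - h), y1 = std::min(ny - 1, y + h);
        const int z0 = std::max(0, z - h), z1 = std::min(nz - 1, z + h);
        std::fill(counts.begin(), counts.end(), 0.0);
        double tot = 0.0;
        for (int k = 0; k < n_off; ++k) {
          const int ax0 = std::max(x0, x0 - ox[k]), ax1 = std::min(x1, x1 - ox[k]);
          const int ay0 = std::max(y0, y0 - oy[k]), ay1 = std::min(y1, y1 - oy[k]);
          const int az0 = std::max(z0, z0 - oz[k]), az1 = std::min(z1, z1 - oz[k]);
          for (int c = az0; c <= az1; ++c) {
            const R_xlen_t base_c = (R_xlen_t)c * nx * ny;
            const R_xlen_t base_c2 = (R_xlen_t)(c + oz[k]) * nx * ny;
            for (int b = ay0; b <= ay1; ++b) {
              const R_xlen_t base = base_c + (R_xlen_t)b * nx;
              const R_xlen_t base2 = base_c2 + (R_xlen_t)(b + oy[k]) * nx;
              for (int a = ax0; a <= ax1; ++a) {
                const int g1 = vol[base + a];
                const int g2 = vol[base2 + a + ox[k]];
                if (g1 > 0 && g2 > 0) {
                  counts[(size_t)(g1 - 1) * G + (g2 - 1)] += 1.0;
                  counts[(size_t)(g2 - 1) * G + (g1 - 1)] += 1.0;
                  tot += 2.0;
                }
              }
            }
          }
        }
        const R_xlen_t v = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (tot <= 0.0) continue;  // maps already 0
        std::fill(qsum.begin(), qsum.end(), 0.0);
        std::fill(qdiff.begin(), qdiff.end(), 0.0);
        double e_energy = 0, e_contrast = 0, e_homog = 0, e_entropy = 0;
        for (int i = 0; i < G; ++i) {
          for (int j = 0; j < G; ++j) {
            const double c = counts[(size_t)i * G + j];
            if (c <= 0.0) continue;
            const double p = c / tot;
            const int d = i > j ? i - j : j - i;
            e_energy += p * p;
            e_contrast += (double)d * d * p;
            e_homog += p / (1.0 + d);
            e_entropy -= p * std::log(p) / LOG2;
            qsum[i + j] += p;
            qdiff[d] += p;
          }
        }
        double e_sent = 0, e_dent = 0;
        for (int k = 0; k <= 2 * G - 2; ++k)
          if (qsum[k] > 0) e_sent -= qsum[k] * std::log(qsum[k]) / LOG2;
        for (int k = 0; k < G; ++k)
          if (qdiff[k] > 0) e_dent -= qdiff[k] * std::log(qdiff[k]) / LOG2;
        ent[v] = e_entropy; sent[v] = e_sent; dent[v] = e_dent;
        ene[v] = e_energy; con[v] = e_contrast; hom[v] = e_homog;
      }
    }
  }
  return List::create(_["entropy"] = ent, _["sum_entropy"] = sent,
                      _["difference_entropy"] = dent, _["energy"] = ene,
                      _["contrast"] = con, _["homogeneity"] = hom);
}
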