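#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Iterative-threshold connected-component puncta detection.
//
// For each cutoff c from max_cutoff down to min_cutoff (step 1): binarize
// unmasked pixels >= c, label connected components in row-major scan order,
// accept components with area > min_region_px whose intensity-weighted
// centroid is not within exclusion_margin of any previously accepted center
// (including centers accepted earlier at the same cutoff). Disk masks of
// radius exclusion_margin around accepted centers are applied from the next
// cutoff onward ("subsequent iterations").
//
// img holds integers in [0, 255]; coordinates are 0-based (row, col).
// [[Rcpp::export]]
DataFrame cpp_detect_puncta(IntegerMatrix img, int max_cutoff, int min_cutoff,
                            int min_region_px, double margin,
                            int connectivity) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<bool> masked(static_cast<size_t>(H) * W, false);
  std::vector<int> visited(static_cast<size_t>(H) * W, 0);
  int stamp = 0;

  std::vector<double> acc_row, acc_col, acc_round;
  std::vector<int> acc_cut, acc_area;

  const int n_off = (connectivity == 4) ? 4 : 8;
  const int off_r[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int off_c[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  std::vector<int> stack, comp;
  const double margin2 = margin * margin;

  for (int cut = max_cutoff; cut >= min_cutoff; --cut) {
    ++stamp;
    std::vector<double> new_row, new_col;  // masks buffered per cutoff
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        const size_t p = static_cast<size_t>(c) * H + r;  // column-major index
        if (masked[p] || visited[p] == stamp || img[p] < cut) continue;
        // flood fill one component
        stack.clear(); comp.clear();
        stack.push_back(static_cast<int>(p));
        visited[p] = stamp;
        while (!stack.empty()) {
          const int q = stack.back(); stack.pop_back();
          comp.push_back(q);
          const int qr = q % H, qc = q / H;
          for (int k = 0; k < n_off; ++k) {
            const int nr = qr + off_r[k], nc = qc + off_c[k];
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            const size_t np = static_cast<size_t>(nc) * H + nr;
            if (masked[np] || visited[np] == stamp || img[np] < cut) continue;
            visited[np] = stamp;
            stack.push_back(static_cast<int>(np));
          }
        }
        const int area = static_cast<int>(comp.size());
        if (area <= min_region_px) continue;
        double wsum = 0.0, wr = 0.0, wc = 0.0;
        for (int q : comp) {
          const double w = img[q];
          wsum += w;
          wr += w * (q % H);
          wc += w * (q / H);
        }
        const double cr = wr / wsum, cc = wc / wsum;
        bool excluded = false;
        for (size_t i = 0; i < acc_row.size(); ++i) {
          const double dr = acc_row[i] - cr, dc = acc_col[i] - cc;
          if (dr * dr + dc * dc <= margin2) { excluded = true; break; }
        }
        if (excluded) continue;
        double maxd2 = 0.0;
        for (int q : comp) {
          const double dr = (q % H) - cr, dc = (q / H) - cc;
          const double d2 = dr * dr + dc * dc;
          if (d2 > maxd2) maxd2 = d2;
        }
        // circularity proxy: component area over the disk spanned by its
        // farthest pixel (1 for a perfect disk, small for elongated shapes)
        const double roundness = maxd2 > 0.0
          ? area / (M_PI * (std::sqrt(maxd2) + 0.5) * (std::sqrt(maxd2) + 0.5))
          : 1.0;
        acc_row.push_back(cr); acc_col.push_back(cc);
        acc_cut.push_back(cut); acc_area.push_back(area);
        acc_round.push_back(roundness);
        new_row.push_back(cr); new_col.push_back(cc);
      }
    }
    // apply this cutoff's masks for all subsequent iterations
    for (size_t i = 0; i < new_row.size(); ++i) {
      const int r0 = std::max(0, static_cast<int>(std::floor(new_row[i] - margin)));
      const int r1 = std::min(H - 1, static_cast<int>(std::ceil(new_row[i] + margin)));
      const int c0 = std::max(0, static_cast<int>(std::floor(new_col[i] - margin)));
      const int c1 = std::min(W - 1, static_cast<int>(std::ceil(new_col[i] + margin)));
      for (int r = r0; r <= r1; ++r)
        for (int c = c0; c <= c1; ++c) {
          const double dr = r - new_row[i], dc = c - new_col[i];
          if (dr * dr + dc * dc <= margin2)
            masked[static_cast<size_t>(c) * H + r] = true;
        }
    }
  }
  return DataFrame::create(_["row"] = acc_row, _["col"] = acc_col,
                           _["detection_cutoff"] = acc_cut,
                           _["area_px"] = acc_area,
                           _["roundness"] = acc_round);
}
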