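# Site-level summaries of a September 2016 seine survey of 20 sand-bed sites
# in the Middle Rio Grande, New Mexico; each 200-m site was sampled with 40
# consecutive seine hauls. Transcribed at printed precision.
# Columns:
#   site          site number (1-20)
#   s_5 ... s_40  observed species richness after 5, 10, 20, 40 hauls (species)
#   s_chao        bias-corrected Chao1 richness estimate at 40 hauls (species)
#   h_75, h_100   hauls needed to reach 75% / 100% of the 40-haul richness
#   prop_run      proportion of the 40 hauls made in run habitat (fraction)
#   mean_depth    mean seine-haul depth (m)
#   wetted_width  wetted width of the site (m)
site,s_5,s_10,s_20,s_40,s_chao,h_75,h_100,prop_run,mean_depth,wetted_width
1,1,6,6,6,7,10,10,0.78,0.17,15
2,3,3,4,4,4,5,12,0.58,0.18,20
3,1,3,6,6,6,16,17,0.67,0.16,9
4,4,5,6,6,6,10,14,0.68,0.18,15
5,3,6,6,8,8.5,7,39,0.41,0.19,10
6,3,3,4,5,5,19,22,0.61,0.18,13
7,0,1,4,4,4,17,20,1.00,0.54,28
8,5,6,6,6,6,5,7,0.48,0.37,30
9,4,5,5,5,5,4,10,0.90,0.40,60
10,3,4,5,5,6,7,18,0.66,0.23,5
11,2,2,3,3,3,16,16,0.76,0.18,9
12,2,3,5,5,5.5,14,20,0.52,0.18,12
13,6,6,6,6,7,3,3,0.55,0.18,3
14,6,8,8,8,8,4,8,0.55,0.17,13
15,8,9,9,9,9,4,10,0.96,0.38,60
16,6,6,8,8,8,4,17,0.78,0.24,100
17,5,5,8,8,8,17,18,0.85,0.37,80
18,2,4,6,7,7.5,20,27,0.90,0.36,40
19,3,8,8,9,9,8,37,0.90,0.27,80
20,6,7,7,9,9.5,9,30,0.83,0.37,60
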