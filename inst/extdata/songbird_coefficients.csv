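species,scale_m,term,beta,se
Canada Jay,1250,Intercept,-4.41,0.83
Canada Jay,1250,coniferous forest,0.04,0.01
Canada Jay,1250,shrubs,0.06,0.03
Wilson's Warbler,1250,Intercept,-2.04,0.37
Wilson's Warbler,1250,herbaceous,-0.06,0.03
Wilson's Warbler,1250,shrubs,0.08,0.02
Savannah Sparrow,4250,Intercept,-5.26,0.81
Savannah Sparrow,4250,herbaceous,0.24,0.07
Golden-Crowned Kinglet,250,Intercept,-6.22,1.39
Golden-Crowned Kinglet,250,coniferous forest,0.05,0.01
Golden-Crowned Kinglet,250,wetland,0.05,0.01
Golden-Crowned Kinglet,250,shrubs,0.04,0.02
Ruby-Crowned Kinglet,1500,Intercept,-4.85,1.22
Ruby-Crowned Kinglet,1500,coniferous forest,0.03,0.01
Ruby-Crowned Kinglet,1500,broadleaf forest,0.73,0.36
Ruby-Crowned Kinglet,1500,wetland,0.04,0.02
Ruby-Crowned Kinglet,1500,shrubs,0.05,0.03
Dark-Eyed Junco,1250,Intercept,-1.56,0.27
Dark-Eyed Junco,1250,herbaceous,-0.14,0.05
Dark-Eyed Junco,1250,shrubs,0.04,0.02
American Robin,1500,Intercept,-0.80,0.37
American Robin,1500,coniferous forest,-0.03,0.01
American Robin,1500,broadleaf forest,0.49,0.26
Hermit Thrush,500,Intercept,-2.36,0.53
Hermit Thrush,500,coniferous forest,0.01,0.01
Hermit Thrush,500,broadleaf forest,0.94,0.33
Hermit Thrush,500,wetland,-0.02,0.02
Pine Siskin,4500,Intercept,-1.02,0.40
Pine Siskin,4500,coniferous forest,0.02,0.01
Pine Siskin,4500,broadleaf forest,-2.13,0.66
American Pipit,250,Intercept,0.21,0.20
American Pipit,250,coniferous forest,-0.08,0.02
American Pipit,250,wetland,-0.03,0.01
American Pipit,250,broadleaf forest,0.73,0.23
Golden-Crowned Sparrow,250,Intercept,-0.11,0.22
Golden-Crowned Sparrow,250,coniferous forest,-0.08,0.02
Golden-Crowned Sparrow,250,wetland,-0.03,0.01
Golden-Crowned Sparrow,250,broadleaf forest,1.28,0.38
Swainson's Thrush,4000,Intercept,-9.52,2.00
Swainson's Thrush,4000,coniferous forest,0.07,0.02
Swainson's Thrush,4000,wetland,0.11,0.04
Swainson's Thrush,4000,shrubs,0.14,0.05
Swainson's Thrush,4000,broadleaf forest,1.47,0.66
Yellow-Rumped Warbler,4500,Intercept,-1.01,0.93
Yellow-Rumped Warbler,4500,coniferous forest,0.03,0.01
Yellow-Rumped Warbler,4500,herbaceous,-0.13,0.06
Chipping Sparrow,250,Intercept,1.05,0.47
Chipping Sparrow,250,coniferous forest,-0.02,0.01
Chipping Sparrow,250,wetland,-0.02,0.01
Chipping Sparrow,250,herbaceous,-0.01,0.01
Varied Thrush,3750,Intercept,-3.79,0.89
Varied Thrush,3750,broadleaf forest,1.94,0.66
Varied Thrush,3750,wetland,-0.11,0.10
Varied Thrush,3750,shrubs,0.05,0.04
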