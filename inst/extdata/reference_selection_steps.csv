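step,reported_name,canonical_name,note
step2,Heterogeneity,heterogeneity,
step2,Rectangular degree,extent,
step2,Elongation,elongation,
step2,Eccentricity,eccentricity,
step3,Fractal dimension,fractal_dimension,
step3,Circularity,circularity,
step3,Spiculation,spiculation,
step3,Area,area,
step3,Correlation,correlation,
step3,Inertia,contrast,
step3,Sum Variance,sum_variance,
step3,Sum entropy,sum_entropy,
step3,Difference Average,difference_average,
step3,Difference Average,difference_variance,printed twice in the source table; second occurrence read as Difference Variance
step3,Difference Entropy,difference_entropy,
step4,Compactness,compactness,
step4,Solidity,solidity,
step4,Entropy of Radial Length Distribution,radial_length_entropy,
step4,Energy,asm,
step4,Sum Average,sum_average,
step4,Information Correlation 2,info_correlation_2,
final,ADC,adc,
final,Slope,slope,
final,SER,ser,
final,Age,age,
final,Entropy,entropy,
final,Inverse Difference,inverse_difference,
final,Information Correlation 1,info_correlation_1,
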