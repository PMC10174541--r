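model,response,subset,r2,rmse,mbe
MLP,contamination,train,0.890,15.948,-2.272
MLP,contamination,test,0.844,20.645,-3.565
MLP,germination,train,0.846,15.383,1.699
MLP,germination,test,0.794,17.219,1.956
GRNN,contamination,train,0.954,11.632,1.572
GRNN,contamination,test,0.886,14.836,-2.735
GRNN,germination,train,0.941,10.724,-1.182
GRNN,germination,test,0.841,14.026,1.898
RBF,contamination,train,0.944,13.737,2.024
RBF,contamination,test,0.863,18.370,-3.870
RBF,germination,train,0.913,11.569,-1.237
RBF,germination,test,0.800,15.369,2.870
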