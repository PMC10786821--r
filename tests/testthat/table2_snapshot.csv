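name,latent_dim,activation,optimizer,learning_rate,dropout,gen_units,disc_units,gcn_units,batch_size,batch_size_alt
base,64,tanh_relu,adam,1e-5,0.2,512,512,128,32,NA
model1,64,leaky_relu,rmsprop,1e-5,0.01,512,512,128,32,NA
model2,64,leaky_relu,rmsprop,1e-4,0.5,512,512,128,128,NA
model3,256,tanh_relu,rmsprop,1e-4,0.5,4092,4092,128,32,512
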